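#' Generate annotated genomes with planted bactofilin/M23 gene pairs
#'
#' Emits a synthetic genome-annotation set for testing the gene-neighborhood
#' screen: per genome, a rank-ordered, non-overlapping gene table on one
#' replicon, where with probability `planted_pair_probability` a
#' bactofilin-domain gene and an M23-peptidase-domain gene are planted at
#' adjacent ranks with a prescribed orientation and intergenic distance
#' (negative = overlap; the default -17 bp mirrors a tightly coupled
#' operon arrangement). Genomes without a planted pair receive a lone
#' bactofilin gene and a lone M23 gene separated by at least one intervening
#' gene, as screen-negative decoys. All other genes carry decoy domain
#' families.
#'
#' @param n_genomes Number of genomes.
#' @param genes_per_genome Genes per genome (>= 6).
#' @param planted_pair_probability Probability a genome carries an adjacent
#'   pair, in `[0, 1]`.
#' @param pair_orientation `"co_directional"`, `"convergent"` or
#'   `"divergent"`.
#' @param pair_intergenic_distance Intergenic distance of planted pairs in
#'   bp; negative values overlap (default -17).
#' @param taxonomy_labels Optional tibble (`genome_id`, `species`,
#'   `lineage`) overriding the generated taxonomy.
#' @param seed Integer seed.
#'
#' @return A list of class `planted_genomes`: `genes` (tibble of gene
#'   records: `genome_id`, `replicon_id`, `gene_id`, `start`, `end`,
#'   `strand`, `protein_id`), `domain_hits` (`protein_id`, `domain_family`,
#'   `evalue`), `taxonomy` (`genome_id`, `species`, `lineage`), and
#'   `planted_truth` (one row per planted pair).
#' @export
#' @examples
#' pg <- generate_genomes(n_genomes = 5, seed = 1)
#' pg$planted_truth
generate_genomes <- function(n_genomes = 50,
                             genes_per_genome = 30,
                             planted_pair_probability = 0.5,
                             pair_orientation = c("co_directional",
                                                  "convergent", "divergent"),
                             pair_intergenic_distance = -17L,
                             taxonomy_labels = NULL,
                             seed = 1L) {
  n_genomes <- stop_if_not_count(n_genomes, "n_genomes")
  genes_per_genome <- stop_if_not_count(genes_per_genome, "genes_per_genome",
                                        min = 6L)
  stop_if_not_scalar_number(planted_pair_probability,
                            "planted_pair_probability", 0, 1)
  pair_orientation <- match.arg(pair_orientation)
  stopifnot(pair_intergenic_distance == round(pair_intergenic_distance))
  pair_intergenic_distance <- as.integer(pair_intergenic_distance)
  min_gene_len <- 300L
  if (pair_intergenic_distance < 0 &&
      -pair_intergenic_distance >= min_gene_len) {
    abort(sprintf(
      "requested overlap (%d bp) is longer than the shortest gene (%d bp)",
      -pair_intergenic_distance, min_gene_len))
  }
  set.seed(new_seed(seed))

  decoy_families <- c("ABC_transporter", "GGDEF", "HTH_regulator",
                      "TonB_receptor", "Sigma54_activ", "PAS_sensor")
  genes <- vector("list", n_genomes)
  hits <- vector("list", n_genomes)
  truth <- vector("list", n_genomes)

  for (g in seq_len(n_genomes)) {
    gid <- sprintf("G%03d", g)
    ng <- genes_per_genome
    lens <- sample(min_gene_len:1500L, ng, replace = TRUE)
    gaps <- sample(50L:200L, ng, replace = TRUE)
    has_pair <- runif(1) < planted_pair_probability
    # placement slots: pair at adjacent ranks i, i+1; decoys well separated
    pair_i <- sample(2:(ng - 2L), 1L)
    strand <- sample(c("+", "-"), ng, replace = TRUE)

    start <- integer(ng); end <- integer(ng)
    pos <- 1000L
    for (i in seq_len(ng)) {
      if (has_pair && i == pair_i + 1L) {
        # place relative to the pair partner: start = prev_end + d + 1
        s <- end[i - 1L] + pair_intergenic_distance + 1L
        # keep rank order (start must exceed previous start)
        s <- max(s, start[i - 1L] + 1L)
      } else {
        s <- pos
      }
      start[i] <- s
      end[i] <- s + lens[i] - 1L
      pos <- end[i] + gaps[i]
    }

    fam <- sample(decoy_families, ng, replace = TRUE)
    if (has_pair) {
      ab <- sample(c(TRUE, FALSE), 1L)   # bactofilin first or second
      fam[pair_i] <- if (ab) "Bactofilin" else "M23_peptidase"
      fam[pair_i + 1L] <- if (ab) "M23_peptidase" else "Bactofilin"
      st <- switch(pair_orientation,
                   co_directional = c("+", "+"),
                   convergent = c("+", "-"),
                   divergent = c("-", "+"))
      strand[pair_i] <- st[1L]; strand[pair_i + 1L] <- st[2L]
    } else {
      # lone decoy family members, >= 1 intervening gene between them
      i_bac <- 2L
      i_m23 <- ng - 1L
      fam[i_bac] <- "Bactofilin"; fam[i_m23] <- "M23_peptidase"
    }

    gene_id <- sprintf("%s_g%03d", gid, seq_len(ng))
    protein_id <- sprintf("%s_p%03d", gid, seq_len(ng))
    genes[[g]] <- tibble(
      genome_id = gid, replicon_id = paste0(gid, "_chr"),
      gene_id = gene_id, start = start, end = end, strand = strand,
      protein_id = protein_id
    )
    hits[[g]] <- tibble(
      protein_id = protein_id, domain_family = fam,
      evalue = 10^runif(ng, -60, -10)
    )
    if (has_pair) {
      bac_i <- if (fam[pair_i] == "Bactofilin") pair_i else pair_i + 1L
      m23_i <- if (bac_i == pair_i) pair_i + 1L else pair_i
      truth[[g]] <- tibble(
        genome_id = gid,
        bactofilin_gene = gene_id[bac_i],
        peptidase_gene = gene_id[m23_i],
        orientation = pair_orientation,
        intergenic_distance = start[pair_i + 1L] - end[pair_i] - 1L
      )
    }
  }

  taxonomy <- taxonomy_labels %||% {
    phyla <- c("Pseudomonadota", "Bacillota", "Actinomycetota",
               "Bacteroidota", "Cyanobacteriota")
    tibble(
      genome_id = sprintf("G%03d", seq_len(n_genomes)),
      species = sprintf("Synthospecies sp%03d", seq_len(n_genomes)),
      lineage = paste("Bacteria",
                      sample(phyla, n_genomes, replace = TRUE),
                      "ClassX", "OrderX", "FamilyX",
                      sprintf("Genus%03d", seq_len(n_genomes)), sep = ";")
    )
  }

  structure(list(
    genes = bind_rows(genes),
    domain_hits = bind_rows(hits),
    taxonomy = taxonomy,
    planted_truth = if (length(purrr::compact(truth)) > 0L) {
      bind_rows(truth)
    } else {
      tibble(genome_id = character(), bactofilin_gene = character(),
             peptidase_gene = character(), orientation = character(),
             intergenic_distance = integer())
    }
  ), class = "planted_genomes")
}

#' @export
print.planted_genomes <- function(x, ...) {
  cat(sprintf("<planted_genomes> %d genomes, %d genes, %d planted pairs\n",
              dplyr::n_distinct(x$genes$genome_id), nrow(x$genes),
              nrow(x$planted_truth)))
  invisible(x)
}
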