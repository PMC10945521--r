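#' Annotate genes with domain families
#'
#' Joins protein domain hits onto gene records, keeping families with
#' `evalue <= evalue_max` (inclusive). Hits referencing unknown proteins are
#' skipped with a warning and counted in the `n_orphan_hits` attribute.
#'
#' @param genes Tibble of gene records (`genome_id`, `replicon_id`,
#'   `gene_id`, `start`, `end`, `strand`, `protein_id`).
#' @param hits Tibble of domain hits (`protein_id`, `domain_family`,
#'   `evalue`).
#' @param evalue_max E-value cutoff (default 1e-5).
#' @return The gene table with a list-column `domain_families` (character
#'   vector per gene, `character(0)` = none).
#' @export
assign_domains <- function(genes, hits, evalue_max = 1e-5) {
  require_columns(genes, c("genome_id", "replicon_id", "gene_id", "start",
                           "end", "strand", "protein_id"), "gene table")
  require_columns(hits, c("protein_id", "domain_family", "evalue"),
                  "domain-hit table")
  stop_if_not_scalar_number(evalue_max, "evalue_max", 0, strict_lower = TRUE)
  if (any(genes$end < genes$start)) abort("gene with end < start")

  orphans <- setdiff(hits$protein_id, genes$protein_id)
  if (length(orphans) > 0L) {
    warn(sprintf("%d domain hit(s) reference unknown proteins; skipped",
                 sum(hits$protein_id %in% orphans)))
  }
  kept <- hits |>
    filter(.data$evalue <= evalue_max,
           .data$protein_id %in% genes$protein_id)
  fam_by_protein <- split(kept$domain_family, kept$protein_id)
  out <- as_tibble(genes)
  out$domain_families <- map(out$protein_id, function(p) {
    unique(fam_by_protein[[p]] %||% character(0))
  })
  attr(out, "n_orphan_hits") <- sum(hits$protein_id %in% orphans)
  out
}

#' Find adjacent gene pairs carrying two domain families
#'
#' Scans each replicon for genes of family `family_a` located immediately
#' upstream or downstream (rank-adjacent: no intervening annotated gene) of
#' a gene of family `family_b`, in either order and any strand combination.
#' Orientation is reported, never filtered on. A gene carrying both
#' families is never paired with itself. The result is independent of input
#' row order (genes are canonically sorted by start within replicon).
#'
#' @param labeled_genes Output of [assign_domains()].
#' @param family_a,family_b Domain family identifiers (defaults
#'   `"Bactofilin"` and `"M23_peptidase"`).
#' @param circular Consider adjacency across the replicon origin
#'   (last-rank/first-rank; default FALSE).
#' @return A tibble of neighbor pairs: `genome_id`, `replicon_id`,
#'   `bactofilin_gene` (family-a member), `peptidase_gene` (family-b
#'   member), `orientation`, `intergenic_distance` (bp; negative =
#'   overlap), `upstream_member` (which gene precedes in genomic
#'   coordinates: `"a"` or `"b"`).
#' @export
find_pairs <- function(labeled_genes,
                       family_a = "Bactofilin",
                       family_b = "M23_peptidase",
                       circular = FALSE) {
  require_columns(labeled_genes, c("genome_id", "replicon_id", "gene_id",
                                   "start", "end", "strand",
                                   "domain_families"), "labeled gene table")
  df <- labeled_genes |>
    arrange(.data$genome_id, .data$replicon_id, .data$start) |>
    mutate(
      has_a = purrr::map_lgl(.data$domain_families, ~ family_a %in% .x),
      has_b = purrr::map_lgl(.data$domain_families, ~ family_b %in% .x)
    )

  pairs <- df |>
    group_by(.data$genome_id, .data$replicon_id) |>
    dplyr::group_map(function(grp, key) {
      n <- nrow(grp)
      if (n < 2L) return(NULL)
      idx <- cbind(seq_len(n - 1L), 2:n)
      if (circular && n > 2L) idx <- rbind(idx, c(n, 1L))
      res <- NULL
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1L]; j <- idx[r, 2L]
        ab <- grp$has_a[i] && grp$has_b[j]
        ba <- grp$has_b[i] && grp$has_a[j]
        if (!ab && !ba) next
        gi <- grp[i, ]; gj <- grp[j, ]
        dist <- gj$start - gi$end - 1L
        orient <- orientation_class(gi$strand, gj$strand)
        if (ab) {
          res <- bind_rows(res, tibble(
            genome_id = key$genome_id, replicon_id = key$replicon_id,
            bactofilin_gene = gi$gene_id, peptidase_gene = gj$gene_id,
            orientation = orient, intergenic_distance = dist,
            upstream_member = "a"))
        }
        if (ba) {
          res <- bind_rows(res, tibble(
            genome_id = key$genome_id, replicon_id = key$replicon_id,
            bactofilin_gene = gj$gene_id, peptidase_gene = gi$gene_id,
            orientation = orient, intergenic_distance = dist,
            upstream_member = "b"))
        }
      }
      res
    }) |>
    bind_rows()

  if (nrow(pairs) == 0L) {
    return(tibble(genome_id = character(), replicon_id = character(),
                  bactofilin_gene = character(), peptidase_gene = character(),
                  orientation = character(), intergenic_distance = integer(),
                  upstream_member = character()))
  }
  # each unordered pair once; a gene never pairs with itself
  pairs |>
    filter(.data$bactofilin_gene != .data$peptidase_gene) |>
    distinct(.data$genome_id, .data$replicon_id, .data$bactofilin_gene,
             .data$peptidase_gene, .keep_all = TRUE)
}

#' Intergenic distance between two adjacent genes
#'
#' For `g1` preceding `g2` by start coordinate on the same replicon
#' (1-based inclusive coordinates): `g2$start - g1$end - 1`. Zero means
#' abutting genes; negative values denote an overlap of that many bp.
#'
#' @param g1,g2 Single gene records (lists or one-row data frames with
#'   `replicon_id`, `start`, `end`).
#' @return Integer distance in bp.
#' @export
#' @examples
#' g1 <- list(replicon_id = "c", start = 100, end = 500)
#' g2 <- list(replicon_id = "c", start = 484, end = 900)
#' intergenic_distance(g1, g2)   # -17: the genes overlap by 17 bp
intergenic_distance <- function(g1, g2) {
  if (!identical(as.character(g1$replicon_id),
                 as.character(g2$replicon_id))) {
    abort("genes lie on different replicons; intergenic distance undefined")
  }
  if (g1$start > g2$start) abort("`g1` must precede `g2` by start coordinate")
  as.integer(g2$start - g1$end - 1)
}

#' Orientation class of an adjacent gene pair
#'
#' For `g1` preceding `g2`: both genes on the same strand are
#' co-directional; `+` then `-` is convergent (head-to-head); `-` then `+`
#' is divergent (tail-to-tail promoters pointing apart).
#'
#' @param strand1,strand2 Strand symbols, `"+"` or `"-"`.
#' @return `"co_directional"`, `"convergent"` or `"divergent"`.
#' @export
orientation_class <- function(strand1, strand2) {
  ok <- c("+", "-")
  if (!(strand1 %in% ok) || !(strand2 %in% ok)) {
    abort(sprintf("invalid strand symbol: '%s'/'%s'", strand1, strand2))
  }
  if (strand1 == strand2) return("co_directional")
  if (strand1 == "+") "convergent" else "divergent"
}

#' Summarize a neighborhood screen at the species and taxon level
#'
#' Deduplicates hits to species (a species is counted once no matter how
#' many genomes or pairs support it) and aggregates counts at a taxonomic
#' rank parsed from semicolon-separated lineage strings
#' (`domain;phylum;class;order;family;genus`). Genomes missing from the
#' taxonomy are counted under `"unclassified"`.
#'
#' @param pairs Pair table from [find_pairs()].
#' @param taxonomy Tibble `genome_id`, `species`, `lineage`.
#' @param rank Aggregation rank (default `"phylum"`).
#' @return A list of class `screen_summary`: `species_count`, `pairs`,
#'   `per_taxon` (tibble `taxon`, `n_species`), `species` (tibble
#'   `species`, `taxon`).
#' @export
summarize_screen <- function(pairs, taxonomy,
                             rank = c("phylum", "domain", "class", "order",
                                      "family", "genus")) {
  rank <- match.arg(rank)
  require_columns(taxonomy, c("genome_id", "species", "lineage"),
                  "taxonomy table")
  rank_i <- match(rank, c("domain", "phylum", "class", "order", "family",
                          "genus"))
  tax <- pairs |>
    distinct(.data$genome_id) |>
    left_join(taxonomy, by = "genome_id") |>
    mutate(
      species = dplyr::coalesce(.data$species, "unclassified"),
      taxon = ifelse(
        is.na(.data$lineage), "unclassified",
        purrr::map_chr(strsplit(.data$lineage %||% "", ";"), function(p) {
          if (length(p) >= rank_i) p[rank_i] else "unclassified"
        })
      )
    ) |>
    distinct(.data$species, .data$taxon)

  per_taxon <- tax |>
    dplyr::count(.data$taxon, name = "n_species") |>
    arrange(dplyr::desc(.data$n_species))

  structure(list(
    species_count = nrow(tax),
    pairs = pairs,
    per_taxon = per_taxon,
    species = tax,
    rank = rank
  ), class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("<screen_summary> %d species with adjacent pairs (%d pairs)\n",
              x$species_count, nrow(x$pairs)))
  print(x$per_taxon)
  invisible(x)
}

#' Export a screen summary as an iTOL annotation dataset
#'
#' Writes a COLORSTRIP annotation file (one record per species, coloured by
#' taxon) ready for upload alongside a phylogenetic tree on the iTOL
#' server. Labels containing the separator are escaped (replaced by `_`)
#' with a warning. [read_itol()] round-trips the species/taxon records.
#'
#' @param summary A `screen_summary`.
#' @param path Output file path.
#' @param label Dataset label shown in iTOL.
#' @return `path`, invisibly.
#' @export
export_itol <- function(summary, path, label = "bactofilin-M23 neighborhood") {
  stopifnot(inherits(summary, "screen_summary"))
  sp <- summary$species
  esc <- function(x) {
    bad <- grepl(",", x, fixed = TRUE)
    if (any(bad)) {
      warn(sprintf("%d label(s) contained the separator; escaped with '_'",
                   sum(bad)))
    }
    gsub(",", "_", x, fixed = TRUE)
  }
  taxa <- sort(unique(sp$taxon))
  palette <- grDevices::hcl.colors(max(length(taxa), 1L), "Dark 3")
  colour <- setNames(palette[seq_along(taxa)], taxa)
  header <- c(
    "DATASET_COLORSTRIP",
    "SEPARATOR COMMA",
    paste0("DATASET_LABEL,", esc(label)),
    "COLOR,#7570b3",
    "STRIP_WIDTH,40",
    "DATA"
  )
  lines <- if (nrow(sp) > 0L) {
    paste(gsub(" ", "_", esc(sp$species)), colour[sp$taxon],
          esc(sp$taxon), sep = ",")
  } else {
    character(0)
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read back an iTOL COLORSTRIP annotation file
#'
#' @param path File written by [export_itol()].
#' @return A tibble `species`, `taxon`.
#' @export
read_itol <- function(path) {
  lines <- readLines(path)
  i <- match("DATA", lines)
  if (is.na(i)) abort("not an iTOL dataset file: no DATA section")
  data_lines <- lines[-seq_len(i)]
  data_lines <- data_lines[nzchar(data_lines)]
  if (length(data_lines) == 0L) {
    return(tibble(species = character(), taxon = character()))
  }
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  tibble(
    species = gsub("_", " ", vapply(parts, `[`, "", 1L)),
    taxon = vapply(parts, `[`, "", 3L)
  )
}
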