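toy_genes <- function() {
  tibble::tibble(
    genome_id = "G1", replicon_id = "chr",
    gene_id = c("g1", "g2", "g3"),
    start = c(100L, 700L, 1500L), end = c(500L, 1200L, 2000L),
    strand = c("+", "+", "-"),
    protein_id = c("p1", "p2", "p3")
  )
}

test_that("domain assignment honours the inclusive e-value cutoff", {
  genes <- toy_genes()
  hits <- tibble::tibble(
    protein_id = c("p1", "p1", "p1", "p2"),
    domain_family = c("Bactofilin", "GGDEF", "PAS_sensor", "M23_peptidase"),
    evalue = c(1e-30, 1e-5, 1e-2, 1e-20)
  )
  lab <- assign_domains(genes, hits, evalue_max = 1e-5)
  expect_setequal(lab$domain_families[[1]], c("Bactofilin", "GGDEF"))
  expect_equal(lab$domain_families[[2]], "M23_peptidase")
  expect_length(lab$domain_families[[3]], 0L)    # no hits -> none

  # empty hit table labels every gene none
  lab0 <- assign_domains(genes, hits[0, ])
  expect_true(all(lengths(lab0$domain_families) == 0L))

  # orphan hits warn and are counted
  orphan <- tibble::tibble(protein_id = "pX", domain_family = "Bactofilin",
                           evalue = 1e-30)
  expect_warning(labO <- assign_domains(genes, orphan), "unknown")
  expect_equal(attr(labO, "n_orphan_hits"), 1L)
})

test_that("screen on planted genomes has perfect recall and precision", {
  pg <- generate_genomes(n_genomes = 50, planted_pair_probability = 0.5,
                         seed = 10)
  lab <- assign_domains(pg$genes, pg$domain_hits)
  pairs <- find_pairs(lab)
  found <- paste(pairs$genome_id, pairs$bactofilin_gene,
                 pairs$peptidase_gene)
  truth <- paste(pg$planted_truth$genome_id,
                 pg$planted_truth$bactofilin_gene,
                 pg$planted_truth$peptidase_gene)
  expect_setequal(found, truth)              # recall 1 and precision 1
  expect_gt(length(truth), 10L)              # the regime is non-trivial

  # every pair is rank-adjacent on its replicon
  ranks <- pg$genes |>
    dplyr::group_by(replicon_id) |>
    dplyr::mutate(rank = rank(start)) |>
    dplyr::ungroup()
  rk <- function(g) ranks$rank[match(g, ranks$gene_id)]
  expect_true(all(abs(rk(pairs$bactofilin_gene) -
                        rk(pairs$peptidase_gene)) == 1))
})

test_that("inserting a decoy between every planted pair kills recall", {
  pg <- generate_genomes(n_genomes = 30, planted_pair_probability = 1,
                         seed = 4)
  lab <- assign_domains(pg$genes, pg$domain_hits)
  base_pairs <- find_pairs(lab)
  expect_equal(nrow(base_pairs), nrow(pg$planted_truth))

  # a decoy gene whose start falls between the pair members' starts breaks
  # rank adjacency
  coords <- pg$genes |> dplyr::select(gene_id, start)
  decoys <- pg$planted_truth |>
    dplyr::left_join(coords, by = c("bactofilin_gene" = "gene_id")) |>
    dplyr::rename(start_bac = start) |>
    dplyr::left_join(coords, by = c("peptidase_gene" = "gene_id")) |>
    dplyr::rename(start_pep = start) |>
    dplyr::mutate(
      replicon_id = paste0(genome_id, "_chr"),
      gene_id = paste0("decoy_", dplyr::row_number()),
      protein_id = paste0("decoyp_", dplyr::row_number()),
      start = (start_bac + start_pep) %/% 2L,    # strictly between the pair
      end = start + 20L, strand = "+"
    ) |>
    dplyr::select(genome_id, replicon_id, gene_id, start, end, strand,
                  protein_id)
  genes2 <- dplyr::bind_rows(pg$genes, decoys)
  lab2 <- assign_domains(genes2, pg$domain_hits)
  expect_equal(nrow(find_pairs(lab2)), 0L)
})

test_that("pair detection is order-invariant and never self-pairs", {
  pg <- generate_genomes(n_genomes = 20, planted_pair_probability = 0.6,
                         seed = 77)
  lab <- assign_domains(pg$genes, pg$domain_hits)
  shuffled <- lab[sample(nrow(lab)), ]
  p1 <- find_pairs(lab) |> dplyr::arrange(genome_id, bactofilin_gene)
  p2 <- find_pairs(shuffled) |> dplyr::arrange(genome_id, bactofilin_gene)
  expect_equal(as.data.frame(p1), as.data.frame(p2))
  expect_true(all(p1$bactofilin_gene != p1$peptidase_gene))

  # a gene carrying both families is not paired with itself
  genes <- toy_genes()
  hits <- tibble::tibble(protein_id = "p2",
                         domain_family = c("Bactofilin", "M23_peptidase"),
                         evalue = c(1e-30, 1e-30))
  both <- find_pairs(assign_domains(genes, hits))
  expect_equal(nrow(both), 0L)
})

test_that("an intervening gene breaks adjacency", {
  genes <- toy_genes()                       # g1, g2, g3 in rank order
  hits <- tibble::tibble(protein_id = c("p1", "p3"),
                         domain_family = c("Bactofilin", "M23_peptidase"),
                         evalue = c(1e-30, 1e-30))
  expect_equal(nrow(find_pairs(assign_domains(genes, hits))), 0L)
})

test_that("intergenic distance follows the 1-based inclusive convention", {
  g <- function(s, e) list(replicon_id = "c", start = s, end = e)
  expect_equal(intergenic_distance(g(100, 500), g(484, 900)), -17L)
  expect_equal(intergenic_distance(g(100, 500), g(501, 900)), 0L)
  expect_equal(intergenic_distance(g(100, 500), g(601, 900)), 100L)
  expect_error(intergenic_distance(list(replicon_id = "a", start = 1, end = 2),
                                   list(replicon_id = "b", start = 5, end = 9)),
               "replicon")
  # coordinate consistency: g1.end + d + 1 = g2.start
  d <- intergenic_distance(g(100, 500), g(484, 900))
  expect_equal(500 + d + 1, 484)
})

test_that("planted pairs reproduce the 17-bp overlap arrangement", {
  pg <- generate_genomes(n_genomes = 20, planted_pair_probability = 1,
                         pair_intergenic_distance = -17L, seed = 6)
  lab <- assign_domains(pg$genes, pg$domain_hits)
  pairs <- find_pairs(lab)
  expect_true(all(pairs$intergenic_distance == -17L))
  expect_true(all(pairs$orientation == "co_directional"))
  # impossible geometry is rejected
  expect_error(generate_genomes(pair_intergenic_distance = -5000),
               "overlap")
})

test_that("orientation classes cover the strand combinations", {
  expect_equal(orientation_class("+", "+"), "co_directional")
  expect_equal(orientation_class("-", "-"), "co_directional")
  expect_equal(orientation_class("+", "-"), "convergent")
  expect_equal(orientation_class("-", "+"), "divergent")
  expect_error(orientation_class("+", "."), "strand")
})

test_that("species are deduplicated and taxon counts aggregate by phylum", {
  pairs <- tibble::tibble(
    genome_id = c("G1", "G2", "G3"), replicon_id = "chr",
    bactofilin_gene = c("a", "b", "c"), peptidase_gene = c("x", "y", "z"),
    orientation = "co_directional", intergenic_distance = -17L,
    upstream_member = "a"
  )
  taxonomy <- tibble::tibble(
    genome_id = c("G1", "G2", "G3"),
    species = c("Sp one", "Sp one", "Sp two"),   # G1, G2 same species
    lineage = c("Bacteria;PhylA;c;o;f;g", "Bacteria;PhylA;c;o;f;g",
                "Bacteria;PhylB;c;o;f;g")
  )
  s <- summarize_screen(pairs, taxonomy)
  expect_equal(s$species_count, 2L)
  expect_equal(sort(s$per_taxon$taxon), c("PhylA", "PhylB"))
  expect_true(all(s$per_taxon$n_species == 1L))

  # permutation invariance and idempotence
  s2 <- summarize_screen(pairs[c(3, 1, 2), ], taxonomy)
  expect_equal(s2$species_count, s$species_count)
  expect_equal(dplyr::arrange(s2$per_taxon, taxon),
               dplyr::arrange(s$per_taxon, taxon))

  # empty input
  s0 <- summarize_screen(pairs[0, ], taxonomy)
  expect_equal(s0$species_count, 0L)
  expect_equal(nrow(s0$per_taxon), 0L)
})

test_that("species counts agree with generator truth", {
  pg <- generate_genomes(n_genomes = 40, planted_pair_probability = 0.7,
                         seed = 15)
  lab <- assign_domains(pg$genes, pg$domain_hits)
  s <- summarize_screen(find_pairs(lab), pg$taxonomy)
  # generated species are distinct per genome
  expect_equal(s$species_count,
               dplyr::n_distinct(pg$planted_truth$genome_id))
})

test_that("iTOL export round-trips the species set", {
  pg <- generate_genomes(n_genomes = 15, planted_pair_probability = 0.8,
                         seed = 8)
  lab <- assign_domains(pg$genes, pg$domain_hits)
  s <- summarize_screen(find_pairs(lab), pg$taxonomy)
  path <- withr::local_tempfile(fileext = ".txt")
  export_itol(s, path)
  back <- read_itol(path)
  expect_setequal(back$species, s$species$species)
  expect_setequal(back$taxon, s$species$taxon)

  # empty summary -> header-only file
  s0 <- summarize_screen(find_pairs(lab)[0, ], pg$taxonomy)
  p0 <- withr::local_tempfile(fileext = ".txt")
  export_itol(s0, p0)
  expect_equal(nrow(read_itol(p0)), 0L)
  expect_true(any(grepl("^DATASET_COLORSTRIP", readLines(p0))))

  # separator escaping warns
  s_bad <- s
  s_bad$species$species[1] <- "weird, name"
  expect_warning(export_itol(s_bad, withr::local_tempfile(fileext = ".txt")),
                 "separator")
})
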