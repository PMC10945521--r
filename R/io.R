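# Readers and writers for the interchange formats shared by the generators
# and the analysis stages. Every writer/reader pair round-trips losslessly
# on generator output.

#' Write and read particle tracks as CSV
#'
#' Columns: `track_id`, `frame`, `t_s` (= frame x dt), `x_um`, `y_um`. The
#' frame interval is recorded in a header comment and restored on read
#' (an explicit `frame_interval` argument overrides it).
#'
#' @param ts A [track_set].
#' @param path CSV file path.
#' @return `write_tracks()`: `path`, invisibly. `read_tracks()`: a
#'   `track_set`.
#' @export
write_tracks <- function(ts, path) {
  dt <- frame_interval(ts)
  df <- as_tibble(ts) |>
    mutate(t_s = .data$frame * dt) |>
    select("track_id", "frame", "t_s", "x_um", "y_um")
  writeLines(sprintf("# frame_interval_s=%.17g", dt), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_tracks
#' @param frame_interval Frame interval in seconds; default: the value in
#'   the file's header comment.
#' @export
read_tracks <- function(path, frame_interval = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(frame_interval) && grepl("^# frame_interval_s=", first)) {
    frame_interval <- as.numeric(sub("^# frame_interval_s=", "", first))
  }
  if (is.null(frame_interval)) {
    abort("`frame_interval` not given and not recorded in the file header")
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  require_columns(df, c("track_id", "frame", "x_um", "y_um"),
                  sprintf("track file '%s'", path))
  if (nrow(df) == 0L) abort(sprintf("no tracks in '%s'", path))
  track_set(df[c("track_id", "frame", "x_um", "y_um")],
            frame_interval = frame_interval)
}

#' Write and read gene records as GFF3
#'
#' Gene records (1-based inclusive coordinates) are exported as GFF3 `gene`
#' features via rtracklayer, with `ID`, `protein_id` and `genome_id`
#' attributes; the replicon is the seqid. Reading parses `gene` and `CDS`
#' features; other feature types are skipped and counted in the
#' `n_skipped_features` attribute.
#'
#' @param genes Tibble of gene records (`genome_id`, `replicon_id`,
#'   `gene_id`, `start`, `end`, `strand`, `protein_id`).
#' @param path GFF3 file path.
#' @return `write_gff3()`: `path`, invisibly. `read_gff3()`: a tibble of
#'   gene records.
#' @export
write_gff3 <- function(genes, path) {
  require_columns(genes, c("genome_id", "replicon_id", "gene_id", "start",
                           "end", "strand", "protein_id"), "gene table")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$protein_id <- genes$protein_id
  gr$genome_id <- genes$genome_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   abort(sprintf("malformed GFF3 '%s': %s", path,
                                 conditionMessage(e)))
                 })
  if (length(gr) == 0L) {
    warn(sprintf("no features in '%s'", path))
    return(tibble(genome_id = character(), replicon_id = character(),
                  gene_id = character(), start = integer(), end = integer(),
                  strand = character(), protein_id = character()))
  }
  types <- as.character(gr$type)
  keep <- types %in% c("gene", "CDS")
  n_skipped <- sum(!keep)
  gr <- gr[keep]
  if (any(BiocGenerics::end(gr) < BiocGenerics::start(gr))) {
    abort(sprintf("feature with end < start in '%s'", path))
  }
  mc <- S4Vectors::mcols(gr)
  out <- tibble(
    genome_id = as.character(mc$genome_id %||%
                               rep(NA_character_, length(gr))),
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    gene_id = as.character(mc$ID),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    protein_id = as.character(mc$protein_id %||%
                                rep(NA_character_, length(gr)))
  )
  attr(out, "n_skipped_features") <- n_skipped
  out
}

#' Read/write domain-hit and taxonomy tables (TSV)
#'
#' Domain hits: `protein_id`, `domain_family`, `evalue`. Taxonomy:
#' `genome_id`, `species`, `lineage` (semicolon-separated ranks).
#'
#' @param hits,taxonomy Tibbles as above.
#' @param path TSV file path.
#' @return Writers return `path` invisibly; readers return tibbles.
#' @export
write_domain_hits <- function(hits, path) {
  require_columns(hits, c("protein_id", "domain_family", "evalue"),
                  "domain-hit table")
  readr::write_tsv(hits, path)
  invisible(path)
}

#' @rdname write_domain_hits
#' @export
read_domain_hits <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  require_columns(df, c("protein_id", "domain_family", "evalue"),
                  sprintf("domain-hit file '%s'", path))
  df
}

#' @rdname write_domain_hits
#' @export
write_taxonomy <- function(taxonomy, path) {
  require_columns(taxonomy, c("genome_id", "species", "lineage"),
                  "taxonomy table")
  readr::write_tsv(taxonomy, path)
  invisible(path)
}

#' @rdname write_domain_hits
#' @export
read_taxonomy <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  require_columns(df, c("genome_id", "species", "lineage"),
                  sprintf("taxonomy file '%s'", path))
  df
}

#' Read/write binding and growth series (CSV)
#'
#' Binding: `concentration_uM`, `response_nm` and optionally `control_nm`.
#' Growth: `time_h`, `od`.
#'
#' @param series,curve Tibbles as above.
#' @param path CSV file path.
#' @return Writers return `path` invisibly; readers return tibbles.
#' @export
write_binding_series <- function(series, path) {
  require_columns(series, c("concentration_uM", "response_nm"),
                  "binding series")
  readr::write_csv(as_tibble(series), path)
  invisible(path)
}

#' @rdname write_binding_series
#' @export
read_binding_series <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("concentration_uM", "response_nm"),
                  sprintf("binding file '%s'", path))
  df
}

#' @rdname write_binding_series
#' @export
write_growth_curve <- function(curve, path) {
  require_columns(curve, c("time_h", "od"), "growth curve")
  readr::write_csv(as_tibble(curve), path)
  invisible(path)
}

#' @rdname write_binding_series
#' @export
read_growth_curve <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("time_h", "od"), sprintf("growth file '%s'", path))
  df
}

#' Ground-truth sidecar files
#'
#' Writes a flat named list of scalars as a plain-text `key = value` file
#' alongside generated data, and reads it back (numbers are restored as
#' numeric).
#'
#' @param truth Named list of scalar values.
#' @param path File path.
#' @return `write_ground_truth()`: `path` invisibly;
#'   `read_ground_truth()`: a named list.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(is.list(truth), !is.null(names(truth)))
  lines <- vapply(names(truth), function(k) {
    v <- truth[[k]]
    sprintf("%s = %s", k,
            if (is.numeric(v)) sprintf("%.17g", v) else as.character(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- lapply(kv, function(p) {
    v <- paste(p[-1L], collapse = " = ")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  setNames(out, vapply(kv, `[`, "", 1L))
}
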