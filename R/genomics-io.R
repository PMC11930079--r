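# BED / bedGraph surfaces. Coordinates are 0-based half-open everywhere in
# this package, matching the on-disk conventions; rtracklayer does the
# parsing and the 1-based GRanges view is converted at the boundary.

granges_to_tbl <- function(gr) {
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr))
}

#' Read genomic domains from a BED file
#'
#' Three required columns (chrom, start, end); an optional 4th column is
#' used as the domain id (otherwise ids `domain_0001`, ... are assigned).
#' `track`/`browser` header lines are tolerated. Records are sorted by
#' (chrom, start).
#'
#' @param path BED file path.
#' @return A tibble of class `genomic_domains`: `chrom`, `start`, `end`
#'   (0-based half-open), `domain_id`, `class_label` (NA until classified).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read BED file: ", path))
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0) {
    warn(paste0("empty BED file: ", path))
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), domain_id = character(),
                          class_label = character())
    class(out) <- c("genomic_domains", class(out))
    return(out)
  }
  tbl <- granges_to_tbl(gr)
  nm <- gr$name
  tbl$domain_id <- if (!is.null(nm) && !all(is.na(nm))) as.character(nm)
                   else sprintf("domain_%04d", seq_along(gr))
  tbl$class_label <- NA_character_
  if (any(tbl$start >= tbl$end)) abort("BED record with start >= end")
  out <- dplyr::arrange(tbl, .data$chrom, .data$start)
  class(out) <- c("genomic_domains", class(out))
  out
}

#' Read a signal track from a bedGraph file
#'
#' Four columns (chrom, start, end, value); intervals must be disjoint
#' within each chromosome. Records are sorted by (chrom, start).
#'
#' @param path bedGraph file path.
#' @param track_name Label carried on the result (default: file name).
#' @return A tibble of class `signal_track`: `chrom`, `start`, `end`
#'   (0-based half-open), `value`; attribute `track_name`.
#' @export
read_bedgraph <- function(path, track_name = basename(path)) {
  if (!file.exists(path)) abort(paste0("cannot read bedGraph file: ", path))
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0) warn(paste0("empty bedGraph file: ", path))
  if (!GenomicRanges::isDisjoint(gr)) abort("overlapping bedGraph intervals")
  tbl <- granges_to_tbl(gr)
  tbl$value <- as.numeric(gr$score)
  if (any(!is.finite(tbl$value))) abort("non-finite bedGraph values")
  if (any(tbl$start >= tbl$end)) abort("bedGraph record with start >= end")
  out <- dplyr::arrange(tbl, .data$chrom, .data$start)
  class(out) <- c("signal_track", class(out))
  attr(out, "track_name") <- track_name
  out
}

#' Write domains / features to BED and a track to bedGraph
#'
#' @param x A `genomic_domains` tibble (4th column: `domain_id` or, if
#'   present and non-NA, `class_label`) or a `signal_track` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name_col <- if ("class_label" %in% names(x) && !all(is.na(x$class_label)))
    x$class_label else x$domain_id
  readr::write_tsv(tibble::tibble(x$chrom, x$start, x$end, name_col),
                   path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
write_bedgraph <- function(x, path) {
  readr::write_tsv(tibble::tibble(x$chrom, x$start, x$end, x$value),
                   path, col_names = FALSE)
  invisible(path)
}

tbl_to_granges <- function(tbl) {
  GenomicRanges::GRanges(tbl$chrom,
                         IRanges::IRanges(start = tbl$start + 1L,
                                          end = tbl$end))
}
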