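# Compartmental-domain enrichment procedure: per-bp domain means,
# scale-regions matrices, k-means ACTIVE/INACTIVE classification, Welch
# enrichment tests and regulatory-feature Spearman correlations.

interval_means <- function(track, query) {
  # mean per-bp signal of each query interval (tibble chrom/start/end),
  # uncovered bp contributing zero
  qgr <- tbl_to_granges(query)
  tgr <- tbl_to_granges(track)
  hits <- GenomicRanges::findOverlaps(qgr, tgr)
  if (length(hits) == 0) return(rep(0, nrow(query)))
  qi <- S4Vectors::queryHits(hits); ti <- S4Vectors::subjectHits(hits)
  ov <- IRanges::pintersect(IRanges::ranges(qgr)[qi], IRanges::ranges(tgr)[ti])
  contrib <- IRanges::width(ov) * track$value[ti]
  sums <- tapply(contrib, factor(qi, levels = seq_len(nrow(query))), sum,
                 default = 0)
  as.numeric(sums) / (query$end - query$start)
}

#' Mean signal per base pair over each domain
#'
#' `sum(value * covered bp) / domain length`; base pairs not covered by the
#' track contribute zero (the `missing_as_zero` policy; with
#' `missing_as_zero = FALSE` the mean is taken over covered bases only).
#'
#' @param track A [read_bedgraph()] signal track.
#' @param domains A [read_bed()] domains tibble.
#' @param missing_as_zero Count uncovered base pairs as signal 0 (default
#'   TRUE).
#' @return Numeric vector of per-domain means, in `domains` row order.
#' @export
domain_mean_signal <- function(track, domains, missing_as_zero = TRUE) {
  m <- interval_means(track, domains)
  if (!missing_as_zero) {
    qgr <- tbl_to_granges(domains)
    cov_bp <- sapply(seq_len(nrow(domains)), function(i) {
      hits <- IRanges::findOverlaps(IRanges::ranges(qgr)[i],
                                    IRanges::ranges(tbl_to_granges(track)))
      if (length(hits) == 0) return(0)
      sum(IRanges::width(IRanges::pintersect(
        rep(IRanges::ranges(qgr)[i], length(hits)),
        IRanges::ranges(tbl_to_granges(track))[S4Vectors::subjectHits(hits)])))
    })
    len <- domains$end - domains$start
    m <- ifelse(cov_bp > 0, m * len / cov_bp, NA_real_)
  }
  m
}

#' Scale-regions signal matrix over domains
#'
#' deepTools-style "scale regions" binning: each domain body is linearly
#' rescaled to `body_bp_scaled` and binned at `bin_size`; upstream and
#' downstream flanks of `flank_bp` are binned at native scale. Every bin is
#' the mean per-bp signal of its source span (uncovered bp count as zero).
#' Flanks running off the chromosome start (or past `chrom_sizes`, if
#' supplied) are truncated and the domain flagged.
#'
#' @param track A `signal_track`.
#' @param domains A `genomic_domains` tibble.
#' @param flank_bp Flank width, bp (default 5e5).
#' @param body_bp_scaled Common rescaled body length, bp (default 1e6).
#' @param bin_size Bin width, bp; must divide both (default 1e4).
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return An object of class `scale_regions_matrix`: list with `values`
#'   (domains x bins matrix), `domain_id`, `bin_scheme`, `truncated`
#'   (logical per domain), `track_name`.
#' @export
scale_regions_matrix <- function(track, domains, flank_bp = 500000,
                                 body_bp_scaled = 1000000, bin_size = 10000,
                                 chrom_sizes = NULL) {
  if (flank_bp %% bin_size != 0 || body_bp_scaled %% bin_size != 0)
    abort("bin_size must divide flank_bp and body_bp_scaled")
  n_flank <- flank_bp / bin_size
  n_body <- body_bp_scaled / bin_size
  n_bins <- 2 * n_flank + n_body
  vals <- matrix(NA_real_, nrow(domains), n_bins)
  truncated <- logical(nrow(domains))
  for (i in seq_len(nrow(domains))) {
    d <- domains[i, ]
    up_edges <- d$start + bin_size * seq(-n_flank, 0)
    body_edges <- d$start + (d$end - d$start) * seq(0, n_body) / n_body
    down_edges <- d$end + bin_size * seq(0, n_flank)
    edges_lo <- c(up_edges[-length(up_edges)], body_edges[-length(body_edges)],
                  down_edges[-length(down_edges)])
    edges_hi <- c(up_edges[-1], body_edges[-1], down_edges[-1])
    lo <- pmax(edges_lo, 0)
    hi <- edges_hi
    if (!is.null(chrom_sizes) && d$chrom %in% names(chrom_sizes))
      hi <- pmin(hi, chrom_sizes[[d$chrom]])
    truncated[i] <- any(lo != edges_lo) || any(hi != edges_hi)
    ok <- hi > lo
    spans <- tibble::tibble(chrom = d$chrom,
                            start = floor(lo[ok]), end = ceiling(hi[ok]))
    # mean over the intended span width; out-of-genome bp contribute zero
    m <- rep(0, n_bins)
    m[ok] <- interval_means(dplyr::filter(track, .data$chrom == d$chrom),
                            spans) * (spans$end - spans$start) /
      (edges_hi[ok] - edges_lo[ok])
    vals[i, ] <- m
  }
  if (truncated_any <- any(truncated))
    warn(sprintf("%d domain(s) had flanks truncated at a chromosome edge",
                 sum(truncated)))
  structure(list(values = vals, domain_id = domains$domain_id,
                 bin_scheme = c(flank_bp = flank_bp,
                                body_bp_scaled = body_bp_scaled,
                                bin_size = bin_size),
                 truncated = truncated,
                 track_name = attr(track, "track_name") %||% "track"),
            class = "scale_regions_matrix")
}

#' @export
print.scale_regions_matrix <- function(x, ...) {
  cat(sprintf("<scale_regions_matrix> %s: %d domains x %d bins (flank %g bp, body -> %g bp, bin %g bp)\n",
              x$track_name, nrow(x$values), ncol(x$values),
              x$bin_scheme["flank_bp"], x$bin_scheme["body_bp_scaled"],
              x$bin_scheme["bin_size"]))
  invisible(x)
}

#' @export
autoplot.scale_regions_matrix <- function(object, ...) {
  sch <- object$bin_scheme
  n_flank <- sch[["flank_bp"]] / sch[["bin_size"]]
  df <- tibble::tibble(bin = seq_len(ncol(object$values)),
                       mean_signal = colMeans(object$values, na.rm = TRUE))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mean_signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(n_flank + 0.5,
                                       ncol(object$values) - n_flank + 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "bin (flank | scaled body | flank)",
                  y = "mean signal per bp", title = object$track_name) +
    ggplot2::theme_minimal()
}

#' Classify domains by k-means on scale-regions signal
#'
#' Stacks one or more scale-regions matrices column-wise (each track's
#' block z-scored column-wise), runs k-means with multiple random restarts
#' under a fixed seed, and names the cluster with the higher grand mean of
#' the first-listed (reference, activating) track `ACTIVE` (the other
#' `INACTIVE`; with `k > 2` the remaining clusters keep numeric labels).
#'
#' @param matrices A `scale_regions_matrix` or list of them (same domain
#'   order).
#' @param k Number of clusters (default 2).
#' @param seed RNG seed for the restarts.
#' @param nstart Number of random restarts (default 10).
#' @return Tibble `domain_id`, `class_label`.
#' @export
kmeans_classify <- function(matrices, k = 2, seed = 1L, nstart = 10L) {
  if (inherits(matrices, "scale_regions_matrix")) matrices <- list(matrices)
  blocks <- purrr::map(matrices, function(m) {
    v <- m$values
    v[!is.finite(v)] <- 0
    s <- apply(v, 2, sd)
    ctr <- sweep(v, 2, colMeans(v))
    sweep(ctr, 2, ifelse(s > 0, s, 1), `/`)
  })
  X <- do.call(cbind, blocks)
  if (nrow(unique(X)) < k) abort("fewer distinct rows than k")
  km <- run_seeded(seed, kmeans(X, centers = k, nstart = nstart,
                                iter.max = 100))
  ref <- blocks[[1]]
  grand <- tapply(rowMeans(ref), km$cluster, mean)
  labels <- as.character(km$cluster)
  hi <- names(grand)[which.max(grand)]
  if (k == 2) {
    lo <- setdiff(names(grand), hi)
    labels[labels == hi] <- "ACTIVE"
    labels[labels == lo] <- "INACTIVE"
  } else {
    labels[labels == hi] <- "HIGH"
  }
  tibble::tibble(domain_id = matrices[[1]]$domain_id, class_label = labels)
}

#' Welch enrichment test between domain classes
#'
#' Two-sided unequal-variance (Welch) t statistic with Welch–Satterthwaite
#' degrees of freedom on per-domain mean signals, plus the mean fold
#' change high/low. When both groups have zero variance and equal means
#' the statistic is 0 with p = 1.
#'
#' @param values_high,values_low Per-domain mean signals for the two
#'   classes (each n >= 2).
#' @return One-row tibble: `t_stat`, `df`, `p_value`, `fold_change`,
#'   `n_high`, `n_low`.
#' @export
enrichment_test <- function(values_high, values_low) {
  if (length(values_high) < 2 || length(values_low) < 2)
    abort("each group needs at least 2 values")
  if (var(values_high) == 0 && var(values_low) == 0 &&
      mean(values_high) == mean(values_low)) {
    t_stat <- 0; df <- length(values_high) + length(values_low) - 2; p <- 1
  } else {
    tt <- t.test(values_high, values_low, var.equal = FALSE)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  }
  tibble::tibble(t_stat = t_stat, df = df, p_value = p,
                 fold_change = mean(values_high) / mean(values_low),
                 n_high = length(values_high), n_low = length(values_low))
}

#' Spearman correlations between two tracks at regulatory features
#'
#' Restricts features to those whose midpoint lies inside any domain,
#' computes the per-feature mean signal of both tracks (uncovered bp as
#' zero) and, per feature class with at least `min_features` usable
#' features, the Spearman rank correlation (average ranks for ties).
#'
#' @param track_a,track_b `signal_track` tibbles.
#' @param features Tibble `chrom`, `start`, `end`, `class` (e.g. promoter,
#'   promoter_flanking, enhancer, open_chromatin).
#' @param domains A `genomic_domains` tibble.
#' @param min_features Minimum usable features per class (default 3);
#'   classes below it are omitted with a warning.
#' @return Tibble `class`, `spearman_rho`, `n_features`.
#' @export
regulatory_correlation <- function(track_a, track_b, features, domains,
                                   min_features = 3L) {
  mid <- floor((features$start + features$end) / 2)
  midtbl <- tibble::tibble(chrom = features$chrom, start = mid, end = mid + 1L)
  hits <- GenomicRanges::findOverlaps(tbl_to_granges(midtbl),
                                      tbl_to_granges(domains))
  inside <- sort(unique(S4Vectors::queryHits(hits)))
  feats <- features[inside, , drop = FALSE]
  if (nrow(feats) == 0) {
    warn("no features fall inside the domains")
    return(tibble::tibble(class = character(), spearman_rho = numeric(),
                          n_features = integer()))
  }
  va <- interval_means(track_a, feats)
  vb <- interval_means(track_b, feats)
  out <- tibble::tibble(class = feats$class, a = va, b = vb) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(spearman_rho = if (dplyr::n() >= min_features)
      cor(.data$a, .data$b, method = "spearman") else NA_real_,
      n_features = dplyr::n(), .groups = "drop")
  dropped <- out$class[is.na(out$spearman_rho) | out$n_features < min_features]
  if (length(dropped) > 0)
    warn(paste0("omitting classes with fewer than ", min_features,
                " usable features: ", paste(dropped, collapse = ", ")))
  dplyr::filter(out, .data$n_features >= min_features,
                !is.na(.data$spearman_rho))
}
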