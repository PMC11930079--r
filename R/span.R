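#' Distance between the two binding-site beads of a conformer
#'
#' Euclidean distance between the designated acetyl-lysine binding-site
#' beads (residues 140 and 433 in the BRD4 numbering; the farthest-from-
#' attachment surface beads for surrogate domains). Symmetric in site
#' order.
#'
#' @param coords A single conformer's n x 3 coordinate matrix (or a one-row
#'   `conformer_set`).
#' @param model The [build_dumbbell_template()] bead model supplying
#'   `site1_index` / `site2_index`.
#' @return Distance in Angstrom.
#' @export
measure_site_distance <- function(coords, model) {
  stopifnot(inherits(model, "bead_model"))
  if (inherits(coords, "conformer_set")) {
    stopifnot(nrow(coords) == 1)
    coords <- coords$coords[[1]]
  }
  coords <- as.matrix(coords)
  i <- model$site1_index; j <- model$site2_index
  if (i < 1 || j < 1 || i > nrow(coords) || j > nrow(coords))
    abort("site index out of range for conformer coordinates")
  sqrt(sum((coords[i, ] - coords[j, ])^2))
}

#' Inter-binding-site distance distribution over an ensemble
#'
#' Computes the site-to-site distance for every conformer and a Gaussian
#' kernel density estimate (Scott's-rule bandwidth) on a grid from 0 to
#' `max(distance) + 3 * bandwidth`.
#'
#' @param conformers A `conformer_set` (typically constraint-filtered).
#' @param model The template bead model (defaults to the one attached to
#'   `conformers`).
#' @param n_grid KDE grid size.
#' @return An object of class `distance_distribution`: list with
#'   `distances`, tibble `kde` (columns `x`, `y`), `n`, `bandwidth`.
#' @export
distance_distribution <- function(conformers, model = NULL, n_grid = 512L) {
  model <- model %||% attr(conformers, "template")
  stopifnot(inherits(model, "bead_model"))
  if (nrow(conformers) < 2) abort("need at least 2 conformers")
  d <- purrr::map_dbl(conformers$coords, measure_site_distance, model = model)
  bw <- tryCatch(bw.nrd(d), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) bw <- max(0.01 * mean(d), 1e-6)  # degenerate sample
  grid <- seq(0, max(d) + 3 * bw, length.out = n_grid)
  dens <- density(d, bw = bw, from = 0, to = max(grid), n = n_grid)
  kde <- tibble::tibble(x = dens$x, y = dens$y)
  structure(list(distances = d, kde = kde, n = length(d), bandwidth = bw),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf(
    "<distance_distribution> n = %d, range [%.1f, %.1f] A, median %.1f A\n",
    x$n, min(x$distances), max(x$distances), median(x$distances)))
  invisible(x)
}

#' Nucleosome-span summary of a distance distribution
#'
#' Fraction of inter-site distances strictly greater than a span threshold
#' (default 57 Angstrom, the length of a nucleosome), plus raw-sample
#' extrema and median.
#'
#' @param dist A [distance_distribution()].
#' @param threshold Span threshold, Angstrom (default 57).
#' @return A one-row tibble of class `span_summary`: `min_d`, `median_d`,
#'   `max_d`, `span_threshold`, `fraction_above`, `n`.
#' @export
span_fraction <- function(dist, threshold = 57) {
  stopifnot(inherits(dist, "distance_distribution"))
  d <- dist$distances
  out <- tibble::tibble(min_d = min(d), median_d = median(d), max_d = max(d),
                        span_threshold = threshold,
                        fraction_above = mean(d > threshold), n = length(d))
  class(out) <- c("span_summary", class(out))
  out
}

#' Export per-model ensemble statistics as a TSV table
#'
#' One row per conformer: model id, inter-site distance, Rg, Dmax and the
#' clash score.
#'
#' @param conformers A `conformer_set`.
#' @param dist The matching [distance_distribution()].
#' @param path Output TSV path (optional; if `NULL` the tibble is returned
#'   without writing).
#' @return The table, invisibly when written.
#' @export
export_distance_table <- function(conformers, dist, path = NULL) {
  if (nrow(conformers) != dist$n)
    abort("conformers and distance distribution have different lengths")
  tab <- tibble::tibble(model = conformers$model,
                        distance = dist$distances,
                        rg = conformers$rg,
                        dmax = conformers$dmax_model,
                        clash_energy = conformers$clash_energy)
  if (nrow(tab) == 0) warn("exporting an empty distance table")
  if (!is.null(path)) {
    readr::write_tsv(tab, path)
    return(invisible(tab))
  }
  tab
}

#' @export
autoplot.distance_distribution <- function(object, threshold = 57, ...) {
  ggplot2::ggplot(object$kde, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "inter-site distance (Å)", y = "density (1/Å)",
                  title = sprintf(
                    "Binding-site separation (n = %d), %.0f%% > %g Å",
                    object$n, 100 * mean(object$distances > threshold),
                    threshold)) +
    ggplot2::theme_minimal()
}

#' Run the default span pipeline
#'
#' Convenience wrapper: build the surrogate dumbbell template, sample
#' excluded-volume conformers, apply the experimental Rg window and Dmax
#' cap, and summarise the inter-site distance distribution.
#'
#' @param n_models Conformers to sample (default 5000).
#' @param seed RNG seed.
#' @param filter A [constraint_filter()].
#' @param threshold Span threshold, Angstrom.
#' @param mode Sampler mode.
#' @param linker_stiffness Linker bond-correlation parameter; defaults to
#'   the calibrated [brd4_linker_stiffness()] so that the simulated
#'   ensemble reproduces the experimentally measured mean radius of
#'   gyration of the tandem-bromodomain construct.
#' @return List with `template`, `conformers` (all sampled), `retained`
#'   (post-filter), `dist`, `summary` (a `span_summary` row also carrying
#'   `n_sampled`/`n_retained`).
#' @export
span_pipeline <- function(n_models = 5000L, seed = 1L,
                          filter = constraint_filter(), threshold = 57,
                          mode = "EXCLUDED_VOLUME",
                          linker_stiffness = brd4_linker_stiffness()) {
  template <- build_dumbbell_template()
  conf <- sample_conformers(template,
                            sampler_config(n_models, seed, mode = mode,
                                           linker_stiffness = linker_stiffness))
  kept <- filter_by_constraints(conf, filter, quiet = TRUE)
  dist <- distance_distribution(kept, template)
  summ <- span_fraction(dist, threshold)
  summ$n_sampled <- nrow(conf)
  summ$n_retained <- nrow(kept)
  list(template = template, conformers = conf, retained = kept,
       dist = dist, summary = summ)
}

#' Calibrated linker stiffness for the BRD4 tandem-bromodomain construct
#'
#' Bond-direction correlation parameter of the excluded-volume linker
#' proposal, calibrated once so that the unfiltered simulated ensemble's
#' mean radius of gyration matches the SAXS-measured 55.4 Angstrom for the
#' BRD4 tandem bromodomains; at this value the ensemble's upper Dmax range
#' is also consistent with the measured 201 Angstrom maximum dimension.
#' With stiffness 0 (a freely jointed chain at C-alpha scale) the simulated
#' ensemble is far more compact (mean Rg ~ 43 Angstrom) than the measured
#' construct.
#'
#' @return The calibrated stiffness (dimensionless).
#' @export
brd4_linker_stiffness <- function() 0.97
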