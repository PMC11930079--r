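# Synthetic-data generators. Each writes a machine-readable ground-truth
# sidecar JSON next to its output so downstream checks consume only
# generator outputs plus sidecars.

#' Simulate a SAXS profile with known ground truth
#'
#' Either the analytic uniform-sphere form factor or the ensemble-averaged
#' Debye profile of a sampled dumbbell ensemble, with multiplicative
#' Gaussian noise (`I * (1 + noise_fraction * eps)`) and a sigma column
#' equal to `noise_fraction * I`. Ground-truth Rg and Dmax are written to
#' `<out>.truth.json`.
#'
#' @param source `"sphere"` or `"dumbbell"`.
#' @param out Output `.dat` path (sidecar at `paste0(out, ".truth.json")`).
#' @param q_grid Momentum transfer grid, 1/Angstrom.
#' @param radius Sphere radius, Angstrom (sphere source).
#' @param n_conformers Ensemble size (dumbbell source, default 50).
#' @param noise_fraction Relative noise level (default 0.01; 0 disables
#'   noise but keeps a nominal sigma column).
#' @param seed RNG seed.
#' @param template Dumbbell template (default [build_dumbbell_template()]).
#' @param linker_stiffness Linker bond correlation used for the dumbbell
#'   ensemble; defaults to the calibrated [brd4_linker_stiffness()] so the
#'   synthetic profile emulates the measured tandem-bromodomain ensemble.
#' @return Invisible list with the profile and the truth record.
#' @export
gen_saxs <- function(source = c("sphere", "dumbbell"), out,
                     q_grid = seq(0.004, 0.35, by = 0.002), radius = 30,
                     n_conformers = 50L, noise_fraction = 0.01, seed = 1L,
                     template = NULL,
                     linker_stiffness = brd4_linker_stiffness()) {
  source <- match.arg(source)
  if (noise_fraction < 0) abort("noise_fraction must be >= 0")
  if (source == "sphere") {
    x <- q_grid * radius
    I <- (3 * (sin(x) - x * cos(x)) / x^3)^2
    truth <- list(source = "sphere", radius = radius,
                  rg = sqrt(3 / 5) * radius, dmax = 2 * radius)
  } else {
    template <- template %||% build_dumbbell_template()
    conf <- sample_conformers(template,
                              sampler_config(n_conformers, seed + 7919L,
                                             linker_stiffness = linker_stiffness))
    prof <- ensemble_average_profile(conf, q_grid)
    I <- prof$intensity / max(prof$intensity)
    # coordinate-space ensemble P(r): histogram of all intra-model pair
    # distances, with the same 1%-of-max tail criterion used by compute_pr
    pd <- unlist(purrr::map(conf$coords, function(xyz) as.numeric(dist(xyz))))
    h <- graphics::hist(pd, breaks = seq(0, max(pd) + 1, by = 1),
                        plot = FALSE)
    below <- h$counts < 0.01 * max(h$counts)
    stays <- rev(cumprod(rev(below))) > 0
    dmax_pr <- if (any(stays)) h$mids[which(stays)[1]] else max(pd)
    truth <- list(source = "dumbbell",
                  rg = sqrt(mean(conf$rg^2)),
                  dmax = max(conf$dmax_model),
                  dmax_pr = dmax_pr,
                  n_conformers = n_conformers)
  }
  sig_frac <- if (noise_fraction > 0) noise_fraction else 0.01
  noisy <- run_seeded(seed,
                      I * (1 + noise_fraction * rnorm(length(I))))
  prof <- saxs_profile(q_grid, noisy, sigma = sig_frac * abs(I) + 1e-12,
                       label = paste0("synthetic ", source))
  write_saxs_profile(prof, out)
  jsonlite::write_json(truth, paste0(out, ".truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(profile = prof, truth = truth))
}

#' Simulate a synthetic genome with planted domain structure
#'
#' Places non-overlapping Mb-scale domains of two signal classes (ACTIVE /
#' INACTIVE) on one synthetic chromosome, emits run-length bedGraph tracks
#' (per-run value = class mean + Gaussian noise at `resolution_bp`
#' resolution), places regulatory features uniformly inside domains, and
#' writes truth labels to a sidecar.
#'
#' @param out_dir Output directory (created if needed). Files:
#'   `domains.bed`, `<track>.bedGraph`, `features.bed`, `truth.json`.
#' @param n_domains Number of domains.
#' @param domain_length_range Min/max domain length, bp.
#' @param gap_bp Gap between consecutive domains, bp.
#' @param class_means Named list: per track, numeric `c(ACTIVE =, INACTIVE =)`
#'   per-bp signal means.
#' @param class_sd Named numeric: per-track Gaussian noise sd.
#' @param feature_density Features per Mb per feature class inside domains.
#' @param feature_classes Feature class names.
#' @param feature_width Feature width, bp.
#' @param resolution_bp Noise run length, bp (default 1000).
#' @param seed RNG seed.
#' @return Invisible list with file paths and the truth tibble.
#' @export
gen_genome <- function(out_dir, n_domains = 60L,
                       domain_length_range = c(6e5, 2e6), gap_bp = 1e5,
                       class_means = list(
                         H3K27ac = c(ACTIVE = 5, INACTIVE = 1),
                         H3K4me1 = c(ACTIVE = 1.5, INACTIVE = 4),
                         BRD4 = c(ACTIVE = 4, INACTIVE = 1)),
                       class_sd = c(H3K27ac = 0.5, H3K4me1 = 0.5, BRD4 = 0.5),
                       feature_density = 5, feature_classes = c(
                         "promoter", "promoter_flanking", "enhancer",
                         "open_chromatin"),
                       feature_width = 1000L, resolution_bp = 1000L,
                       seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_seeded(seed, {
    lens <- round(runif(n_domains, domain_length_range[1],
                        domain_length_range[2]) / resolution_bp) * resolution_bp
    starts <- cumsum(c(gap_bp, head(lens, -1) + gap_bp))
    classes <- sample(rep(c("ACTIVE", "INACTIVE"), length.out = n_domains))
    domains <- tibble::tibble(chrom = "chrS", start = as.integer(starts),
                              end = as.integer(starts + lens),
                              domain_id = sprintf("domain_%04d",
                                                  seq_len(n_domains)),
                              class_label = classes)
    tracks <- purrr::imap(class_means, function(means, nm) {
      rows <- purrr::pmap(domains, function(chrom, start, end, domain_id,
                                            class_label) {
        edges <- seq(start, end, by = resolution_bp)
        vals <- means[[class_label]] +
          class_sd[[nm]] * rnorm(length(edges) - 1)
        tibble::tibble(chrom = chrom, start = as.integer(head(edges, -1)),
                       end = as.integer(edges[-1]),
                       value = pmax(vals, 0))
      })
      tr <- dplyr::bind_rows(rows)
      class(tr) <- c("signal_track", class(tr))
      attr(tr, "track_name") <- nm
      tr
    })
    feats <- purrr::pmap(domains, function(chrom, start, end, domain_id,
                                           class_label) {
      n_per <- rpois(length(feature_classes),
                     feature_density * (end - start) / 1e6)
      cls <- rep(feature_classes, n_per)
      if (length(cls) == 0) return(NULL)
      pos <- floor(runif(length(cls), start, end - feature_width))
      tibble::tibble(chrom = chrom, start = as.integer(pos),
                     end = as.integer(pos + feature_width), class = cls)
    })
    features <- dplyr::bind_rows(feats)
    if (nrow(features) == 0)
      features <- tibble::tibble(chrom = character(), start = integer(),
                                 end = integer(), class = character())
    features <- dplyr::arrange(features, .data$start)
    list(domains = domains, tracks = tracks, features = features)
  })
  paths <- list(domains = file.path(out_dir, "domains.bed"),
                features = file.path(out_dir, "features.bed"),
                truth = file.path(out_dir, "truth.json"))
  dom_out <- res$domains
  dom_out$class_label <- NA_character_  # truth goes to the sidecar only
  write_bed(dom_out, paths$domains)
  readr::write_tsv(tibble::tibble(res$features$chrom, res$features$start,
                                  res$features$end, res$features$class),
                   paths$features, col_names = FALSE)
  for (nm in names(res$tracks)) {
    paths[[nm]] <- file.path(out_dir, paste0(nm, ".bedGraph"))
    write_bedgraph(res$tracks[[nm]], paths[[nm]])
  }
  jsonlite::write_json(
    list(seed = seed,
         labels = setNames(as.list(res$domains$class_label),
                           res$domains$domain_id)),
    paths$truth, auto_unbox = TRUE)
  invisible(list(paths = paths, domains = res$domains,
                 features = res$features))
}

#' Simulate a noisy titration plate from an equilibrium model
#'
#' Solves the noise-free titration, applies multiplicative Gaussian noise
#' per replicate, writes a CSV plate (`conc_uM`, `rep1`, ...) and a sidecar
#' with the noise-free curve's fitted EC50 and peak.
#'
#' @param model A [bivalent_model()] or [ternary_model()].
#' @param out Output CSV path (sidecar at `paste0(out, ".truth.json")`).
#' @param grid Titrant concentration grid, micromolar.
#' @param noise_fraction Relative noise (default 0.02).
#' @param replicates Technical replicates per point (default 3).
#' @param seed RNG seed.
#' @return Invisible list with the plate tibble and truth record.
#' @export
gen_titration <- function(model, out,
                          grid = 10^seq(-3, 3, length.out = 20),
                          noise_fraction = 0.02, replicates = 3L, seed = 1L) {
  if (replicates < 1) abort("replicates must be >= 1")
  res <- if (inherits(model, "bivalent_model"))
    solve_bivalent_titration(model, grid)
  else solve_ternary_scaffold(model, grid)
  truth_fit <- fit_hook_curve(res$conc, res$signal)
  plate <- run_seeded(seed, {
    reps <- purrr::map(seq_len(replicates), function(i)
      res$signal * (1 + noise_fraction * rnorm(length(grid))))
    names(reps) <- paste0("rep", seq_len(replicates))
    dplyr::bind_cols(tibble::tibble(conc_uM = res$conc),
                     tibble::as_tibble(reps))
  })
  readr::write_csv(plate, out)
  truth <- list(ec50_rise = truth_fit$ec50_rise,
                peak_conc = truth_fit$peak_conc,
                peak_signal = max(res$signal),
                model = class(model)[1], noise_fraction = noise_fraction,
                seed = seed)
  jsonlite::write_json(truth, paste0(out, ".truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(plate = plate, truth = truth, curve = res))
}
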