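# Equilibrium mass-balance models for the two proximity assays: bivalent
# engagement of one multi-acetylated ligand by both reader domains of a
# single protein (BRET geometry), and one bivalent protein bridging
# epitopes on donor- and acceptor-bead nucleosomes (AlphaScreen geometry).
# Both produce the bell-shaped "hook effect": signal rises with titrant,
# then collapses when binding sites are saturated monovalently.

#' Bivalent (intramolecular ring-closure) binding model
#'
#' One protein with two binding sites A and B; a ligand carrying two
#' epitopes can occupy either site alone or close the ring and occupy both.
#' Ring closure is modelled with an effective concentration `c_eff`
#' multiplying the second, intramolecular association (standard avidity
#' formalism).
#'
#' @param kd_a,kd_b Site dissociation constants, micromolar.
#' @param c_eff Effective concentration for ring closure, micromolar.
#' @param p_total Total protein concentration, micromolar.
#' @return A `bivalent_model` list.
#' @export
bivalent_model <- function(kd_a, kd_b, c_eff, p_total) {
  vals <- c(kd_a = kd_a, kd_b = kd_b, c_eff = c_eff, p_total = p_total)
  if (any(!is.finite(vals)) || any(vals[c("kd_a", "kd_b", "p_total")] <= 0) ||
      c_eff < 0)
    abort("kd_a, kd_b, p_total must be > 0 and c_eff >= 0")
  structure(as.list(vals), class = "bivalent_model")
}

#' Ternary (bead-scaffolding) binding model
#'
#' One bivalent scaffold protein P bridging a donor-bead epitope D and an
#' acceptor-bead epitope A: species P, P.D, P.A and the signal-generating
#' bridge D.P.A.
#'
#' @param kd_d,kd_a2 Dissociation constants of the scaffold sites for the
#'   donor and acceptor epitopes, micromolar.
#' @param d_total,a_total Total epitope concentrations, micromolar.
#' @return A `ternary_model` list.
#' @export
ternary_model <- function(kd_d, kd_a2, d_total, a_total) {
  vals <- c(kd_d = kd_d, kd_a2 = kd_a2, d_total = d_total, a_total = a_total)
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort("all ternary model parameters must be > 0")
  structure(as.list(vals), class = "ternary_model")
}

new_titration_result <- function(species, signal, kind) {
  out <- dplyr::bind_cols(species, tibble::tibble(signal = signal))
  class(out) <- c("titration_result", class(out))
  attr(out, "kind") <- kind
  peak_i <- which.max(out$signal)
  attr(out, "peak_conc") <- out$conc[peak_i]
  out
}

#' Solve the bivalent hook-effect titration
#'
#' At each total ligand concentration the free-ligand concentration is
#' found by a bracketed monotone root of the ligand mass balance (relative
#' tolerance 1e-10), then all species follow analytically:
#' `P.L(A) = P L / kd_a`, `P.L(B) = P L / kd_b`,
#' `P.L(cyclic) = P L c_eff / (kd_a kd_b)`,
#' `P.L.L = P L^2 / (kd_a kd_b)`. The proximity signal is the cyclic
#' (bivalently engaged) fraction `[P.L cyclic] / p_total`.
#'
#' @param model A [bivalent_model()].
#' @param ligand_concs Increasing grid of total ligand concentrations,
#'   micromolar.
#' @return A tibble of class `titration_result`: columns `conc`, `l_free`,
#'   `p_free`, `pl_a`, `pl_b`, `pl_cyclic`, `pll`, `signal`; attribute
#'   `peak_conc`.
#' @export
solve_bivalent_titration <- function(model, ligand_concs) {
  stopifnot(inherits(model, "bivalent_model"))
  conc <- as.numeric(ligand_concs)
  if (any(conc <= 0) || is.unsorted(conc, strictly = TRUE))
    abort("ligand_concs must be positive and strictly increasing")
  ka <- model$kd_a; kb <- model$kd_b; ce <- model$c_eff; pt <- model$p_total

  species_at <- function(L) {
    denom <- 1 + L / ka + L / kb + L * ce / (ka * kb) + L^2 / (ka * kb)
    P <- pt / denom
    list(P = P, pla = P * L / ka, plb = P * L / kb,
         plc = P * L * ce / (ka * kb), pll = P * L^2 / (ka * kb))
  }
  rows <- purrr::map(conc, function(lt) {
    resid <- function(L) {
      s <- species_at(L)
      L + s$pla + s$plb + s$plc + 2 * s$pll - lt
    }
    L <- uniroot(resid, c(0, lt), tol = lt * 1e-12)$root
    s <- species_at(L)
    tibble::tibble(conc = lt, l_free = L, p_free = s$P, pl_a = s$pla,
                   pl_b = s$plb, pl_cyclic = s$plc, pll = s$pll)
  })
  species <- dplyr::bind_rows(rows)
  new_titration_result(species, species$pl_cyclic / pt, "bivalent")
}

#' Solve the ternary bead-scaffolding titration
#'
#' The scaffold protein is titrated against fixed donor and acceptor
#' epitope totals. For each total protein concentration the coupled mass
#' balances for free D and free A are solved by damped fixed-point
#' iteration inside a bracketed monotone root on free P (relative
#' tolerance 1e-10). Signal is the bridge concentration
#' `[D.P.A] = P D A / (kd_d kd_a2)`.
#'
#' @param model A [ternary_model()].
#' @param scaffold_concs Increasing grid of total scaffold protein
#'   concentrations, micromolar.
#' @param max_iter Inner fixed-point iteration cap.
#' @return A tibble of class `titration_result`: columns `conc`, `p_free`,
#'   `d_free`, `a_free`, `pd`, `pa`, `dpa`, `signal` (= `dpa`, micromolar);
#'   attribute `peak_conc`.
#' @export
solve_ternary_scaffold <- function(model, scaffold_concs, max_iter = 10000L) {
  stopifnot(inherits(model, "ternary_model"))
  conc <- as.numeric(scaffold_concs)
  if (any(conc <= 0) || is.unsorted(conc, strictly = TRUE))
    abort("scaffold_concs must be positive and strictly increasing")
  kd <- model$kd_d; ka <- model$kd_a2
  dt <- model$d_total; at <- model$a_total

  free_da <- function(P) {
    D <- dt; A <- at
    for (i in seq_len(max_iter)) {
      Dn <- dt / (1 + P / kd + P * A / (kd * ka))
      An <- at / (1 + P / ka + P * Dn / (kd * ka))
      # half-step damping keeps the alternating iteration contractive
      Dn <- 0.5 * (D + Dn); An <- 0.5 * (A + An)
      if (abs(Dn - D) <= 1e-12 * dt && abs(An - A) <= 1e-12 * at) {
        D <- Dn; A <- An
        return(c(D, A))
      }
      D <- Dn; A <- An
    }
    abort("ternary mass-balance iteration failed to converge")
  }
  rows <- purrr::map(conc, function(pt) {
    resid <- function(P) {
      da <- free_da(P)
      P * (1 + da[1] / kd + da[2] / ka + da[1] * da[2] / (kd * ka)) - pt
    }
    P <- uniroot(resid, c(0, pt), tol = pt * 1e-12)$root
    da <- free_da(P)
    D <- da[1]; A <- da[2]
    tibble::tibble(conc = pt, p_free = P, d_free = D, a_free = A,
                   pd = P * D / kd, pa = P * A / ka,
                   dpa = P * D * A / (kd * ka))
  })
  species <- dplyr::bind_rows(rows)
  new_titration_result(species, species$dpa, "ternary")
}

#' @export
autoplot.titration_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$conc, y = .data$signal)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = attr(object, "peak_conc"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "titrant (µM, log scale)",
                  y = if (attr(object, "kind") == "bivalent")
                    "bivalently engaged fraction" else "bridge species (µM)",
                  title = sprintf("Hook-effect titration (peak at %.3g µM)",
                                  attr(object, "peak_conc"))) +
    ggplot2::theme_minimal()
}

#' Corrected BRET ratio in milli-BRET units
#'
#' `1000 * (exp_610 / exp_450 - ctrl_610 / ctrl_450)`: acceptor/donor
#' emission ratio of the experimental sample minus that of the
#' donor-only control, scaled so one mBU is a corrected ratio of 0.001.
#' Vectorised.
#'
#' @param exp_610,exp_450 Experimental emissions at 610 and 450 nm.
#' @param ctrl_610,ctrl_450 Control (no-acceptor) emissions.
#' @return Corrected BRET ratio in mBU.
#' @export
corrected_bret_ratio <- function(exp_610, exp_450, ctrl_610, ctrl_450) {
  if (any(exp_450 == 0) || any(ctrl_450 == 0))
    abort("zero denominator in BRET ratio")
  1000 * (exp_610 / exp_450 - ctrl_610 / ctrl_450)
}

#' Background-correct and normalize AlphaScreen counts
#'
#' Per concentration group: average the technical replicates, subtract the
#' mean of the negative-control counts, then divide every group by the
#' maximum corrected value (so the curve maximum is 1).
#'
#' @param plate Tibble with a `conc_uM` column and one column per technical
#'   replicate of raw Alpha counts.
#' @param negative_controls Numeric vector of raw negative-control counts.
#' @return Tibble with `conc_uM`, `mean_counts`, `corrected`, `normalized`.
#' @export
normalize_alpha <- function(plate, negative_controls) {
  if (length(negative_controls) < 1) abort("need at least one negative control")
  rep_cols <- setdiff(names(plate), "conc_uM")
  if (length(rep_cols) < 1) abort("plate must have replicate columns")
  mean_counts <- rowMeans(as.matrix(plate[, rep_cols]))
  corrected <- mean_counts - mean(negative_controls)
  if (all(corrected <= 0)) abort("normalization undefined: no corrected signal > 0")
  tibble::tibble(conc_uM = plate$conc_uM, mean_counts = mean_counts,
                 corrected = corrected, normalized = corrected / max(corrected))
}

#' Empirical EC50 and peak of a hook-shaped titration curve
#'
#' The peak is the grid argmax of the signal. The rising-limb EC50 comes
#' from a four-parameter log-logistic fit restricted to points at
#' concentrations at or below the peak; the truncation point is located on
#' a 3-point running mean of the signal so a single noisy point cannot
#' clip the fit window.
#'
#' @param conc Concentration grid, micromolar (>= 5 points).
#' @param signal Signal values, same length.
#' @return One-row tibble of class `hook_fit`: `ec50_rise`, `peak_conc`,
#'   `hill`, `at_boundary` (TRUE when the signal is still rising at the
#'   last grid point, in which case a warning is issued).
#' @export
fit_hook_curve <- function(conc, signal) {
  conc <- as.numeric(conc); signal <- as.numeric(signal)
  if (length(conc) < 5) abort("need at least 5 titration points")
  if (length(conc) != length(signal)) abort("conc and signal lengths differ")
  peak_i <- which.max(signal)
  peak_conc <- conc[peak_i]
  at_boundary <- peak_i == length(conc)
  if (at_boundary)
    warn("signal is still rising at the last grid point; peak at boundary")
  smoothed <- as.numeric(stats::filter(signal, rep(1 / 3, 3), sides = 2))
  smoothed[is.na(smoothed)] <- signal[is.na(smoothed)]
  cut_conc <- conc[which.max(smoothed)]
  rising <- conc <= cut_conc
  if (sum(conc < cut_conc) < 3)
    abort("fewer than 3 rising points below the empirical maximum")
  x <- conc[rising]; y <- signal[rising]
  ymax <- max(y); ymin <- min(y)
  half <- ymin + (ymax - ymin) / 2
  ec50_start <- x[which.min(abs(y - half))]
  fit <- minpack.lm::nlsLM(
    y ~ c0 + (d0 - c0) / (1 + (ec50 / x)^h),
    start = list(c0 = ymin, d0 = ymax, ec50 = ec50_start, h = 1),
    lower = c(-Inf, -Inf, min(x) * 1e-3, 0.1),
    upper = c(Inf, Inf, max(x) * 1e3, 20),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  out <- tibble::tibble(ec50_rise = unname(cf["ec50"]), peak_conc = peak_conc,
                        hill = unname(cf["h"]), at_boundary = at_boundary)
  class(out) <- c("hook_fit", class(out))
  out
}

#' Fold change between two dissociation constants
#'
#' Affinity fold gain of a tighter interaction relative to a weaker one
#' (`kd_weak / kd_tight`), rounded to one decimal as conventionally
#' reported.
#'
#' @param kd_weak,kd_tight Dissociation constants in the same units.
#' @param digits Decimal places for rounding (default 1).
#' @return Numeric fold change.
#' @examples
#' kd_fold_change(76, 17)  # 4.5
#' kd_fold_change(76, 24)  # 3.2
#' @export
kd_fold_change <- function(kd_weak, kd_tight, digits = 1) {
  if (any(kd_weak <= 0) || any(kd_tight <= 0)) abort("Kd values must be > 0")
  round(kd_weak / kd_tight, digits)
}
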