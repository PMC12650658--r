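#' Construct a dissociation-equilibrium model
#'
#' Two schemes for a homotrimeric protein T built from subunits M:
#' * `"T3M"`   - direct trimer-monomer equilibrium T = 3M with
#'   \eqn{K_d = [M]^3/[T]} (units M^2);
#' * `"T3_D2_M"` - trimer via a dimeric intermediate, T = D + M (K1, units M)
#'   and D = 2M (K2, units M). K1*K2 plays the role of Kd: sending K2 to
#'   infinity with K1*K2 fixed recovers the T3M fractions.
#'
#' @param scheme `"T3M"` or `"T3_D2_M"`.
#' @param kd Dissociation constant in M^2 (scheme `"T3M"`).
#' @param k1,k2 Stepwise constants in M (scheme `"T3_D2_M"`).
#' @return An `equilibrium_model`.
#' @examples
#' equilibrium_model("T3M", kd = 5.2e-16)
#' @export
equilibrium_model <- function(scheme = c("T3M", "T3_D2_M"), kd = NULL,
                              k1 = NULL, k2 = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "T3M") {
    if (!is_scalar_number(kd) || kd <= 0) stopf("kd must be a positive number (M^2)")
    m <- list(scheme = scheme, kd = kd)
  } else {
    if (!is_scalar_number(k1) || k1 <= 0 || !is_scalar_number(k2) || k2 <= 0) {
      stopf("k1 and k2 must be positive numbers (M)")
    }
    m <- list(scheme = scheme, k1 = k1, k2 = k2, kd = k1 * k2)
  }
  structure(m, class = "equilibrium_model")
}

#' @export
print.equilibrium_model <- function(x, ...) {
  if (x$scheme == "T3M") {
    cat(sprintf("<equilibrium_model> T = 3M, Kd = %.3g M^2\n", x$kd))
  } else {
    cat(sprintf("<equilibrium_model> T = D + M = 3M, K1 = %.3g M, K2 = %.3g M (K1*K2 = %.3g M^2)\n",
                x$k1, x$k2, x$kd))
  }
  invisible(x)
}

# Positive root of the subunit mass balance for one total concentration.
solve_monomer <- function(model, c_tot) {
  f <- if (model$scheme == "T3M") {
    function(M) M + 3 * M^3 / model$kd - c_tot
  } else {
    function(M) M + 2 * M^2 / model$k2 + 3 * M^3 / (model$k1 * model$k2) - c_tot
  }
  # f is strictly increasing on [0, c_tot] with f(0) < 0 <= f(c_tot).
  M <- stats::uniroot(f, c(0, c_tot), tol = c_tot * 1e-15)$root
  # Newton polish to machine precision of the mass balance.
  fp <- if (model$scheme == "T3M") {
    function(M) 1 + 9 * M^2 / model$kd
  } else {
    function(M) 1 + 4 * M / model$k2 + 9 * M^2 / (model$k1 * model$k2)
  }
  for (i in 1:3) M <- M - f(M) / fp(M)
  max(M, 0)
}

#' Species concentrations and subunit-mass fractions at equilibrium
#'
#' Solves the subunit mass balance `M + 2D + 3T = c_tot` for the unique
#' positive monomer concentration (bracketed root-solve, then Newton polish;
#' mass conservation holds to better than 1e-10 relative). Fractions are
#' subunit-mass fractions `M/c_tot`, `2D/c_tot`, `3T/c_tot`.
#'
#' @param model An `equilibrium_model`.
#' @param c_tot Total subunit concentration(s) in M (> 0); vectorised.
#' @return For scalar `c_tot`, a `species_fractions` list with `M`, `D`, `T`
#'   (molar concentrations) and `f_monomer`, `f_dimer`, `f_trimer`; for
#'   vector input, a data frame with one row per concentration.
#' @examples
#' species_fractions(equilibrium_model("T3M", kd = 5.2e-16), 4.0e-8)
#' @export
species_fractions <- function(model, c_tot) {
  stopifnot(inherits(model, "equilibrium_model"))
  if (any(!is.finite(c_tot)) || any(c_tot <= 0)) stopf("c_tot must be positive")
  one <- function(ct) {
    M <- solve_monomer(model, ct)
    if (model$scheme == "T3M") {
      D <- 0
      T3 <- M^3 / model$kd
    } else {
      D <- M^2 / model$k2
      T3 <- M^3 / (model$k1 * model$k2)
    }
    c(M = M, D = D, T = T3,
      f_monomer = M / ct, f_dimer = 2 * D / ct, f_trimer = 3 * T3 / ct)
  }
  if (length(c_tot) == 1L) {
    v <- one(c_tot)
    structure(c(as.list(v), list(c_tot = c_tot, scheme = model$scheme)),
              class = "species_fractions")
  } else {
    out <- as.data.frame(t(vapply(c_tot, one, numeric(6))))
    out$c_tot <- c_tot
    out
  }
}

#' @export
print.species_fractions <- function(x, ...) {
  cat(sprintf("<species_fractions> c_tot = %.3g M (%s): monomer %.1f%%, dimer %.1f%%, trimer %.1f%%\n",
              x$c_tot, x$scheme, 100 * x$f_monomer, 100 * x$f_dimer, 100 * x$f_trimer))
  invisible(x)
}

#' Monomer fraction as a function of total subunit concentration
#'
#' Vectorised convenience wrapper around [species_fractions()].
#'
#' @inheritParams species_fractions
#' @return Numeric vector of monomer subunit-mass fractions.
#' @export
monomer_fraction <- function(model, c_tot) {
  vapply(c_tot, function(ct) species_fractions(model, ct)$f_monomer, numeric(1))
}

#' Construct a titration dataset
#'
#' @param c_tot Total subunit concentrations (M, > 0).
#' @param f_m Observed monomer fractions in `[0, 1]`.
#' @param technique Technique tag per record (default `"synthetic"`).
#' @param weight Positive fitting weights (default 1).
#' @return A `titration_dataset` data frame.
#' @export
titration_dataset <- function(c_tot, f_m, technique = "synthetic", weight = 1) {
  if (any(c_tot <= 0)) stopf("c_tot must be positive")
  if (any(f_m < 0 | f_m > 1)) stopf("f_m must lie in [0, 1]")
  if (any(weight <= 0)) stopf("weights must be positive")
  out <- data.frame(c_tot = c_tot, f_m = f_m,
                    technique = rep_len(technique, length(c_tot)),
                    weight = rep_len(weight, length(c_tot)),
                    stringsAsFactors = FALSE)
  class(out) <- c("titration_dataset", "data.frame")
  out
}

#' Read a titration CSV (`c_tot_M,f_monomer,technique,weight`)
#'
#' @param path CSV path; `technique` and `weight` columns are optional.
#' @return A `titration_dataset`.
#' @export
read_titration <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("c_tot_M", "f_monomer") %in% names(d))) {
    stopf("titration CSV must have columns c_tot_M and f_monomer")
  }
  titration_dataset(d$c_tot_M, d$f_monomer,
                    technique = d$technique %||% "file",
                    weight = d$weight %||% 1)
}

#' Fit dissociation constants to titration data
#'
#' Minimises the weighted least-squares loss
#' \eqn{\sum_i w_i (f_{m,i} - f_{model}(c_{tot,i}))^2} over `log10(Kd)`
#' (bounded scalar search on `[-20, -10]` for scheme `"T3M"`; bounded 2-d
#' search over `log10(K1)`, `log10(K2)` for `"T3_D2_M"`). Confidence
#' intervals come from a case-resampling bootstrap with a fixed seed.
#'
#' @param data A `titration_dataset` (or data frame with `c_tot`, `f_m`, and
#'   optional `technique`, `weight`).
#' @param scheme `"T3M"` or `"T3_D2_M"`.
#' @param n_bootstrap Bootstrap replicates for the percentile CI (default
#'   200; 0 disables).
#' @param seed Seed for the bootstrap resampling.
#' @return A `dissociation_fit`: list with `model` (fitted
#'   `equilibrium_model`), `kd`, `log10_kd`, `ci` (2.5/97.5 percentiles, or
#'   `NULL`), `rss`, `residuals_by_technique`, `data`, `n_bootstrap`, `seed`.
#' @export
fit_dissociation <- function(data, scheme = c("T3M", "T3_D2_M"),
                             n_bootstrap = 200L, seed = 1L) {
  scheme <- match.arg(scheme)
  data <- as.data.frame(data)
  if (!all(c("c_tot", "f_m") %in% names(data))) stopf("data needs columns c_tot and f_m")
  if (nrow(data) < 4L) stopf("need at least 4 titration points")
  span <- log10(max(data$c_tot) / min(data$c_tot))
  if (!is.finite(span) || span < 2) {
    stopf("titration must span at least 2 decades of concentration (got %.2f)", span)
  }
  w <- data$weight %||% rep(1, nrow(data))

  fit_once <- function(d, wt) {
    loss_t3m <- function(lk) {
      m <- equilibrium_model("T3M", kd = 10^lk)
      sum(wt * (d$f_m - monomer_fraction(m, d$c_tot))^2)
    }
    if (scheme == "T3M") {
      opt <- stats::optimize(loss_t3m, c(-20, -10), tol = 1e-9)
      list(model = equilibrium_model("T3M", kd = 10^opt$minimum), rss = opt$objective)
    } else {
      loss2 <- function(p) {
        m <- equilibrium_model("T3_D2_M", k1 = 10^p[1], k2 = 10^p[2])
        sum(wt * (d$f_m - monomer_fraction(m, d$c_tot))^2)
      }
      # Start from the T3M fit split evenly across the two steps.
      lk <- stats::optimize(loss_t3m, c(-20, -10), tol = 1e-6)$minimum
      opt <- stats::optim(c(lk / 2, lk / 2), loss2, method = "L-BFGS-B",
                          lower = c(-16, -16), upper = c(2, 2))
      list(model = equilibrium_model("T3_D2_M", k1 = 10^opt$par[1], k2 = 10^opt$par[2]),
           rss = opt$value)
    }
  }

  main <- fit_once(data, w)
  resid <- data$f_m - monomer_fraction(main$model, data$c_tot)
  tech <- data$technique %||% rep("all", nrow(data))
  resid_by_tech <- vapply(split(resid, tech), function(r) sqrt(mean(r^2)), numeric(1))

  ci <- NULL
  boot_kd <- NULL
  if (n_bootstrap > 0L) {
    boot_kd <- with_seed(seed, vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(nrow(data), replace = TRUE)
      tryCatch(fit_once(data[idx, , drop = FALSE], w[idx])$model$kd,
               error = function(e) NA_real_)
    }, numeric(1)))
    ci <- stats::quantile(boot_kd, c(0.025, 0.975), na.rm = TRUE)
  }
  structure(list(model = main$model, kd = main$model$kd,
                 log10_kd = log10(main$model$kd), ci = ci,
                 bootstrap_kd = boot_kd, rss = main$rss,
                 residuals_by_technique = resid_by_tech,
                 data = data, n_bootstrap = n_bootstrap, seed = seed),
            class = "dissociation_fit")
}

#' @export
print.dissociation_fit <- function(x, ...) {
  cat(sprintf("<dissociation_fit> %s: Kd = %.3g M^2 (rss %.3g, n = %d)\n",
              x$model$scheme, x$kd, x$rss, nrow(x$data)))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap 95%% CI: [%.3g, %.3g] M^2 (%d reps, seed %d)\n",
                x$ci[1], x$ci[2], x$n_bootstrap, x$seed))
  }
  invisible(x)
}

#' Hydrodynamics of a spheroid: Perrin friction and Stokes-Einstein diffusion
#'
#' The hydrodynamic radius of an ellipsoid of revolution with polar semi-axis
#' `a = r_polar` and equatorial semi-axis `b = r_equatorial`:
#' * prolate (a > b, p = b/a):
#'   \eqn{R_h = a\sqrt{1-p^2} / \ln[(1+\sqrt{1-p^2})/p]}
#' * oblate (a < b, p = a/b):
#'   \eqn{R_h = b\sqrt{1-p^2} / \arctan(\sqrt{1-p^2}/p)}
#' * sphere limit: \eqn{R_h} equals the radius.
#' The translational diffusion coefficient follows from Stokes-Einstein,
#' \eqn{D = k_B T / (6\pi\eta R_h)}, reported in um^2/s.
#'
#' @param r_polar,r_equatorial Semi-axes in angstrom (> 0).
#' @param temperature Absolute temperature in K (default 293.15, i.e. 20 C).
#' @param viscosity Solvent viscosity in Pa s (default water at 20 C,
#'   1.002e-3).
#' @return A `hydro_spheroid`: list with the inputs plus `shape`, `r_hydro`
#'   (angstrom) and `d_trans` (um^2/s).
#' @examples
#' perrin_hydro(24, 17.6)   # prolate monomer-like spheroid: D ~ 109 um^2/s
#' perrin_hydro(20, 41.3)   # oblate trimer-like disk:       D ~ 63 um^2/s
#' @export
perrin_hydro <- function(r_polar, r_equatorial, temperature = 293.15,
                         viscosity = 1.002e-3) {
  if (r_polar <= 0 || r_equatorial <= 0) stopf("radii must be positive")
  if (temperature <= 0 || viscosity <= 0) stopf("temperature and viscosity must be positive")
  a <- r_polar; b <- r_equatorial
  ratio <- a / b
  if (abs(ratio - 1) < 1e-9) {
    shape <- "sphere"
    r_h <- a
  } else if (a > b) {
    shape <- "prolate"
    p <- b / a
    xi <- sqrt(1 - p^2)
    r_h <- a * xi / log((1 + xi) / p)
  } else {
    shape <- "oblate"
    p <- a / b
    xi <- sqrt(1 - p^2)
    r_h <- b * xi / atan(xi / p)
  }
  kb <- 1.380649e-23
  d_m2s <- kb * temperature / (6 * pi * viscosity * r_h * 1e-10)
  structure(list(r_polar = r_polar, r_equatorial = r_equatorial,
                 temperature = temperature, viscosity = viscosity,
                 shape = shape, r_hydro = r_h, d_trans = d_m2s * 1e12),
            class = "hydro_spheroid")
}

#' @export
print.hydro_spheroid <- function(x, ...) {
  cat(sprintf("<hydro_spheroid> %s (%.1f x %.1f A): R_h = %.2f A, D = %.1f um^2/s at %.1f K\n",
              x$shape, x$r_polar, x$r_equatorial, x$r_hydro, x$d_trans, x$temperature))
  invisible(x)
}
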