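# Quantitative analysis of the validation assays: logistic dose-response
# fitting to IC50, Cheng-Prusoff conversion to Ki, Monte-Carlo uncertainty
# propagation, Boltzmann melt-curve fitting to Tm, and the 3-SD
# thermal-shift significance call.

#' Enzyme assay conditions
#'
#' @param substrate_conc substrate concentration in M (default 1 mM, the
#'   esterase-assay condition).
#' @param km Michaelis constant of the enzyme for the substrate, in M.
#'   Required for the Cheng-Prusoff conversion; there is no default.
#' @param enzyme_conc enzyme concentration in M (informational; default
#'   5 nM).
#' @return list of class `"assay_conditions"`.
#' @export
assay_conditions <- function(substrate_conc = 1e-3, km = NULL,
                             enzyme_conc = 5e-9) {
  stopifnot(substrate_conc > 0, enzyme_conc > 0)
  if (!is.null(km)) stopifnot(km > 0)
  structure(list(substrate_conc = substrate_conc, km = km,
                 enzyme_conc = enzyme_conc),
            class = "assay_conditions")
}

logistic_response <- function(conc, ic50, hill) {
  1 / (1 + (conc / ic50)^hill)
}

#' Fit a normalized dose-response curve to IC50
#'
#' Least-squares fit of `response = 1 / (1 + ([I]/IC50)^hill)` (top fixed
#' at 1, bottom at 0, Hill slope free but reported) with multi-start
#' initialization of IC50 over a log-spaced grid spanning the concentration
#' range; the best converged start by residual norm wins.
#'
#' @param concentrations inhibitor concentrations in M, strictly
#'   increasing, at least 5 points.
#' @param responses normalized activities (control = 1).
#' @return list of class `"inhibition_fit"`: `ic50` (M), `hill`, `rss`,
#'   `converged`, `fitted`.
#' @export
fit_dose_response <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses),
            all(concentrations > 0))
  if (length(concentrations) < 5L) {
    stop("need at least 5 concentration points")
  }
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be strictly increasing")
  }
  rho <- suppressWarnings(stats::cor(concentrations, responses,
                                     method = "spearman"))
  if (!is.na(rho) && rho > -0.3) {
    warning("responses are not clearly decreasing with concentration")
  }
  dat <- data.frame(conc = concentrations, resp = responses)
  grid <- exp(seq(log(min(concentrations)), log(max(concentrations)),
                  length.out = 7L))
  best <- NULL
  for (start_ic50 in grid) {
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      resp ~ 1 / (1 + (conc / exp(log_ic50))^hill), data = dat,
      start = list(log_ic50 = log(start_ic50), hill = 1),
      lower = c(log(min(concentrations)) - 12, 0.1),
      upper = c(log(max(concentrations)) + 12, 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )), error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(ic50 = exp(cf[["log_ic50"]]), hill = cf[["hill"]],
                   rss = rss, converged = fit$convInfo$isConv,
                   fitted = as.numeric(stats::fitted(fit)))
    }
  }
  if (is.null(best)) {
    return(structure(list(ic50 = NA_real_, hill = NA_real_, rss = NA_real_,
                          converged = FALSE, fitted = NULL),
                     class = "inhibition_fit"))
  }
  structure(best, class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<inhibition_fit: not converged>\n")
  } else {
    cat(sprintf("<inhibition_fit: IC50 %.4g M, hill %.2f, rss %.3g>\n",
                x$ic50, x$hill, x$rss))
  }
  invisible(x)
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' `Ki = IC50 / (1 + [S]/Km)` for competitive inhibition.
#'
#' @param ic50 IC50 in M (or any unit; Ki comes back in the same unit).
#' @param conditions an [assay_conditions()] with `km` set.
#' @return Ki, same unit as `ic50`.
#' @export
cheng_prusoff <- function(ic50, conditions) {
  if (is.null(conditions$km)) {
    stop("Km is required for the Cheng-Prusoff conversion; ",
         "set assay_conditions(km = ...) explicitly")
  }
  ic50 / (1 + conditions$substrate_conc / conditions$km)
}

#' Monte-Carlo uncertainty for Ki
#'
#' Each cycle perturbs every response with Gaussian noise of standard
#' deviation `max(rel_noise * response, replicate_sd)` (floored relative
#' noise), refits the dose-response model and converts to Ki; the mean and
#' standard deviation over converged cycles are reported.
#'
#' @param concentrations,responses the dose-response data (M, normalized).
#' @param conditions an [assay_conditions()] with `km` set.
#' @param n_cycles Monte-Carlo cycles (default 100).
#' @param rel_noise relative noise floor (default 0.05, i.e. at least 5%
#'   uncertainty assumed in the data).
#' @param replicate_sd optional per-point replicate SDs.
#' @param seed RNG seed.
#' @return list of class `"mc_ki"`: `ki` (point estimate from the
#'   unperturbed fit), `ki_mean`, `ki_sd`, `ic50`, `hill`, `n_converged`.
#' @export
monte_carlo_ki <- function(concentrations, responses, conditions,
                           n_cycles = 100L, rel_noise = 0.05,
                           replicate_sd = NULL, seed = 1L) {
  base <- fit_dose_response(concentrations, responses)
  if (!isTRUE(base$converged)) stop("base dose-response fit did not converge")
  sd_vec <- pmax(rel_noise * abs(responses),
                 if (is.null(replicate_sd)) 0 else replicate_sd)
  set.seed(seed)
  kis <- rep(NA_real_, n_cycles)
  for (i in seq_len(n_cycles)) {
    pert <- responses + stats::rnorm(length(responses), 0, sd_vec)
    fit <- suppressWarnings(tryCatch(
      fit_dose_response(concentrations, pert), error = function(e) NULL))
    if (!is.null(fit) && isTRUE(fit$converged)) {
      kis[i] <- cheng_prusoff(fit$ic50, conditions)
    }
  }
  ok <- !is.na(kis)
  if (mean(ok) < 0.5) {
    stop("more than half of the Monte-Carlo cycles failed to converge (",
         sum(!ok), "/", n_cycles, ")")
  }
  structure(list(
    ki = cheng_prusoff(base$ic50, conditions),
    ki_mean = mean(kis[ok]), ki_sd = stats::sd(kis[ok]),
    ic50 = base$ic50, hill = base$hill, n_converged = sum(ok)
  ), class = "mc_ki")
}

#' @export
print.mc_ki <- function(x, ...) {
  cat(sprintf("<Ki %.4g M +- %.2g (MC over %d cycles; IC50 %.4g M, hill %.2f)>\n",
              x$ki, x$ki_sd, x$n_converged, x$ic50, x$hill))
  invisible(x)
}

#' Fit a DSF melt curve to Tm with the Boltzmann sigmoid
#'
#' Data inside the fit window are min-max normalized and fitted to
#' `F(T) = B + (A - B) / (1 + exp((Tm - T)/s))`; the low/high plateaus `B`
#' and `A`, midpoint `Tm` and slope `s` are estimated.
#'
#' @param temperatures temperatures in deg C.
#' @param fluorescence fluorescence signal (arbitrary units).
#' @param window fit window in deg C (default `c(40, 68)`).
#' @return list of class `"tm_fit"`: `tm`, `slope`, `plateau_low`,
#'   `plateau_high` (normalized units), `converged`, `at_edge` (Tm within
#'   half a degree of the window boundary), `rss`.
#' @export
fit_boltzmann_tm <- function(temperatures, fluorescence, window = c(40, 68)) {
  stopifnot(length(temperatures) == length(fluorescence))
  keep <- temperatures >= window[1] & temperatures <= window[2]
  if (sum(keep) < 10L) stop("need at least 10 points inside the fit window")
  tt <- temperatures[keep]
  ff <- fluorescence[keep]
  rng <- range(ff)
  if (diff(rng) <= 0) stop("flat signal inside the fit window")
  fn <- (ff - rng[1]) / diff(rng)
  tm0 <- tt[which.min(abs(fn - 0.5))]
  dat <- data.frame(t = tt, f = fn)
  fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
    f ~ B + (A - B) / (1 + exp((tm - t) / s)), data = dat,
    start = list(A = 1, B = 0, tm = tm0, s = 2),
    lower = c(-0.5, -0.5, window[1], 0.01),
    upper = c(1.5, 1.5, window[2], 30),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )), error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(tm = NA_real_, slope = NA_real_,
                          plateau_low = NA_real_, plateau_high = NA_real_,
                          converged = FALSE, at_edge = NA, rss = NA_real_),
                     class = "tm_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(
    tm = cf[["tm"]], slope = cf[["s"]],
    plateau_low = cf[["B"]], plateau_high = cf[["A"]],
    converged = fit$convInfo$isConv,
    at_edge = cf[["tm"]] < window[1] + 0.5 || cf[["tm"]] > window[2] - 0.5,
    rss = sum(stats::residuals(fit)^2)
  ), class = "tm_fit")
}

#' @export
print.tm_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<tm_fit: not converged>\n")
  } else {
    cat(sprintf("<tm_fit: Tm %.2f C, slope %.2f C%s>\n", x$tm, x$slope,
                if (isTRUE(x$at_edge)) " [at window edge]" else ""))
  }
  invisible(x)
}

#' Thermal-shift significance call
#'
#' `delta_tm = sample_tm - mean(reference)`; the shift is significant when
#' its magnitude exceeds 3 standard deviations of the reference replicates
#' (sample SD, n - 1).
#'
#' @param sample_tm fitted Tm of the ligand condition, deg C.
#' @param reference_tms at least 3 replicate Tm values of the reference
#'   (apo) condition.
#' @return list with `delta_tm`, `reference_mean`, `reference_sd`,
#'   `significant`.
#' @export
delta_tm_call <- function(sample_tm, reference_tms) {
  if (length(reference_tms) < 3L) {
    stop("at least 3 reference replicates required")
  }
  m <- mean(reference_tms)
  s <- stats::sd(reference_tms)
  d <- sample_tm - m
  list(delta_tm = d, reference_mean = m, reference_sd = s,
       significant = abs(d) > 3 * s)
}
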