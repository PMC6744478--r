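#' Kinetic parameters of a 1:1 binding model
#'
#' @param ka association rate constant, 1/(M s).
#' @param kd dissociation rate constant, 1/s.
#' @param Rmax saturating response, RU.
#' @return `xlcal_kinetics` list with `ka`, `kd`, `Rmax` and the derived
#'   `KD = kd / ka` (molar).
#' @export
kinetic_params <- function(ka, kd, Rmax) {
  stopifnot(ka > 0, kd >= 0, Rmax > 0)   # kd = 0: no measurable dissociation
  structure(list(ka = ka, kd = kd, Rmax = Rmax, KD = kd / ka),
            class = "xlcal_kinetics")
}

#' @export
print.xlcal_kinetics <- function(x, ...) {
  cat(sprintf("<1:1 kinetics> ka %.3g /M/s, kd %.3g /s, Rmax %.3g RU, KD %.3g M (%.3g nM)\n",
              x$ka, x$kd, x$Rmax, x$KD, x$KD * 1e9))
  invisible(x)
}

# closed-form 1:1 Langmuir response at times t (association then dissociation)
.langmuir_response <- function(ka, kd, Rmax, conc, t, t_assoc_end) {
  kobs <- conc * ka + kd
  req <- conc * ka * Rmax / kobs
  r <- req * (1 - exp(-kobs * pmin(t, t_assoc_end)))
  r_end <- req * (1 - exp(-kobs * t_assoc_end))
  dis <- t > t_assoc_end
  r[dis] <- r_end * exp(-kd * (t[dis] - t_assoc_end))
  r
}

#' Simulate a 1:1 Langmuir sensorgram
#'
#' Association phase
#' `R(t) = Req (1 - exp(-(C ka + kd) t))` with
#' `Req = C ka Rmax / (C ka + kd)`, followed by exponential dissociation
#' `R(t) = R(t_assoc) exp(-kd (t - t_assoc))`. Optional i.i.d. Gaussian
#' noise.
#'
#' @param params a [kinetic_params()].
#' @param conc analyte concentration, molar.
#' @param t_assoc,t_dissoc phase durations, seconds.
#' @param dt sampling interval, seconds.
#' @param noise_sd Gaussian noise standard deviation, RU (0 = noiseless).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param label curve label.
#' @return `xlcal_sensorgram`: list with `time`, `response`, `conc`,
#'   `t_assoc_end`, `label`.
#' @export
simulate_1to1 <- function(params, conc, t_assoc = 240, t_dissoc = 240,
                          dt = 1, noise_sd = 0, seed = 1L,
                          label = sprintf("%.3gM", conc)) {
  stopifnot(inherits(params, "xlcal_kinetics"), conc > 0,
            t_assoc > 0, t_dissoc > 0)
  if (dt >= t_assoc + t_dissoc) stop("dt must be smaller than the trace duration")
  t <- seq(0, t_assoc + t_dissoc, by = dt)
  r <- .langmuir_response(params$ka, params$kd, params$Rmax, conc, t, t_assoc)
  if (noise_sd > 0) {
    set.seed(seed)
    r <- r + stats::rnorm(length(r), 0, noise_sd)
  }
  structure(list(time = t, response = r, conc = conc,
                 t_assoc_end = t_assoc, label = label),
            class = "xlcal_sensorgram")
}

#' Globally fit a 1:1 model to multi-concentration sensorgrams
#'
#' Nonlinear least squares (Levenberg-Marquardt on log-parameters, which
#' keeps ka, kd and Rmax positive) over all curves simultaneously,
#' sharing one (ka, kd, Rmax) triple. Initialization is data-driven: kd
#' from the log-linear slope of the dissociation tail of the
#' highest-concentration curve, Rmax and KD from the equilibrium
#' plateaus via a coarse grid, then refined.
#'
#' @param curves list of `xlcal_sensorgram` at >= 2 distinct analyte
#'   concentrations.
#' @return `xlcal_fit`: list with `params` ([kinetic_params()]),
#'   `residual_rms` (per curve, RU), `converged`, `n_curves`.
#' @export
fit_1to1 <- function(curves) {
  if (length(curves) < 2) stop("need at least 2 curves at distinct concentrations")
  concs <- vapply(curves, function(s) s$conc, numeric(1))
  if (anyDuplicated(concs)) stop("analyte concentrations must be distinct")

  # kd init: log-slope of the dissociation tail, highest concentration
  hi <- curves[[which.max(concs)]]
  dis <- hi$time > hi$t_assoc_end & hi$response > 1e-3 * max(hi$response)
  kd0 <- 1e-3
  if (sum(dis) >= 3) {
    sl <- unname(stats::coef(stats::lm(log(hi$response[dis]) ~ hi$time[dis]))[2])
    if (is.finite(sl) && sl < 0) kd0 <- -sl
  }
  rmax0 <- 1.5 * max(vapply(curves, function(s) max(s$response), numeric(1)))
  # ka init: coarse grid minimizing SSE with kd0, rmax0 fixed
  sse <- function(ka, kd, rmax) {
    sum(vapply(curves, function(s) {
      sum((s$response - .langmuir_response(ka, kd, rmax, s$conc,
                                           s$time, s$t_assoc_end))^2)
    }, numeric(1)))
  }
  ka_grid <- 10^seq(2, 9, by = 0.5)
  ka0 <- ka_grid[which.min(vapply(ka_grid, sse, numeric(1),
                                  kd = kd0, rmax = rmax0))]

  resid_fn <- function(theta) {
    ka <- exp(theta[1]); kd <- exp(theta[2]); rmax <- exp(theta[3])
    unlist(lapply(curves, function(s) {
      s$response - .langmuir_response(ka, kd, rmax, s$conc,
                                      s$time, s$t_assoc_end)
    }))
  }
  fit <- minpack.lm::nls.lm(
    par = log(c(ka0, kd0, rmax0)), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  theta <- fit$par
  params <- kinetic_params(exp(theta[1]), exp(theta[2]), exp(theta[3]))
  rms <- vapply(curves, function(s) {
    sqrt(mean((s$response - .langmuir_response(
      params$ka, params$kd, params$Rmax, s$conc, s$time,
      s$t_assoc_end))^2))
  }, numeric(1))
  structure(list(params = params, residual_rms = rms,
                 converged = fit$info %in% 1:4, info = fit$info,
                 n_curves = length(curves)),
            class = "xlcal_fit")
}

#' @export
print.xlcal_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  %d curve(s), residual RMS %.3g RU%s\n", x$n_curves,
              mean(x$residual_rms),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Normalize a blocking curve to a negative control
#'
#' Pointwise ratio of a test sensorgram to a negative-control
#' sensorgram, the normalization used for antibody-blocking SPR series.
#' The control is linearly interpolated onto the test time grid; control
#' samples below `floor` are masked (NA) rather than divided.
#'
#' @param test_signal,control_signal `xlcal_sensorgram` objects.
#' @param floor smallest control response considered divisible, RU.
#' @return data.frame `time`, `ratio` (NA where masked).
#' @export
normalize_blocking <- function(test_signal, control_signal, floor = 1e-9) {
  ctrl <- stats::approx(control_signal$time, control_signal$response,
                        xout = test_signal$time, rule = 2)$y
  ok <- ctrl >= floor
  if (!any(ok)) stop("control signal entirely below floor; nothing to normalize")
  ratio <- rep(NA_real_, length(ctrl))
  ratio[ok] <- test_signal$response[ok] / ctrl[ok]
  data.frame(time = test_signal$time, ratio = ratio)
}

#' Fold difference between two dissociation constants
#'
#' @param kd_a,kd_b equilibrium dissociation constants (same units).
#' @return List: `ratio` (kd_a / kd_b) and `fold` (ratio rounded to one
#'   significant figure, the convention for quoting "n-fold"
#'   differences).
#' @export
fold_change <- function(kd_a, kd_b) {
  stopifnot(kd_a > 0, kd_b > 0)
  ratio <- kd_a / kd_b
  list(ratio = ratio, fold = signif(ratio, 1))
}

#' Write / read sensorgram sets as CSV
#'
#' Columns: `time_s`, `response_RU`, `conc_M`, `label`.
#'
#' @param curves list of `xlcal_sensorgram`.
#' @param path CSV path.
#' @export
write_sensorgrams <- function(curves, path) {
  rows <- lapply(curves, function(s) {
    data.frame(time_s = s$time, response_RU = s$response,
               conc_M = s$conc, label = s$label,
               t_assoc_end = s$t_assoc_end)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_sensorgrams
#' @export
read_sensorgrams <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, factor(df$label, levels = unique(df$label))),
         function(d) {
           structure(list(time = d$time_s, response = d$response_RU,
                          conc = d$conc_M[1],
                          t_assoc_end = d$t_assoc_end[1],
                          label = d$label[1]),
                     class = "xlcal_sensorgram")
         })
}
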