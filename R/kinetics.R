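# 1:1 Langmuir biolayer-interferometry sensorgrams: simulation, global and
# per-trace nonlinear least-squares fitting, and 4PL titration (EC50) fits.

# closed-form 1:1 model: association then dissociation
response_1to1 <- function(t, conc, kon, koff, rmax, t_assoc) {
  kd <- koff / kon
  kobs <- kon * conc + koff
  req <- rmax * conc / (conc + kd)
  r_end <- req * (1 - exp(-kobs * t_assoc))
  ifelse(t <= t_assoc,
         req * (1 - exp(-kobs * t)),
         r_end * exp(-koff * (t - t_assoc)))
}

#' Simulate 1:1 binding sensorgrams
#'
#' Association phase R(t) = Rmax C/(C+KD) (1 - exp(-(kon C + koff) t));
#' dissociation R(t) = R(t_assoc) exp(-koff t). Gaussian noise of standard
#' deviation \code{noise_sd} (response units) is added with the given seed,
#' so traces are fully deterministic.
#'
#' @param kon Association rate, 1/(M s).
#' @param koff Dissociation rate, 1/s.
#' @param rmax Maximal response, response units (nm shift).
#' @param concentrations Analyte concentrations, molar.
#' @param t_assoc,t_dissoc Phase lengths, seconds.
#' @param dt Sampling interval, seconds.
#' @param noise_sd Gaussian noise SD in response units (0 = noiseless).
#' @param seed Integer seed for the noise.
#' @return A \code{SensorgramSet}: \code{time}, \code{t_assoc},
#'   \code{concentrations}, \code{responses} (matrix, one column per
#'   concentration), \code{noise_sd}, and the true parameters used.
#' @export
#' @examples
#' s <- simulate_sensorgrams(1e5, 1.5e-4, 1, 125e-9 / 2^(0:6))
#' dim(s$responses)
simulate_sensorgrams <- function(kon, koff, rmax, concentrations,
                                 t_assoc = 180, t_dissoc = 180, dt = 1,
                                 noise_sd = 0, seed = 1) {
  if (kon <= 0 || koff <= 0 || rmax <= 0 || t_assoc <= 0 || t_dissoc <= 0)
    stop("rates, Rmax and phase lengths must be positive", call. = FALSE)
  if (any(concentrations <= 0))
    stop("concentrations must be positive", call. = FALSE)
  time <- seq(0, t_assoc + t_dissoc, by = dt)
  resp <- vapply(concentrations, function(cc)
    response_1to1(time, cc, kon, koff, rmax, t_assoc),
    numeric(length(time)))
  if (noise_sd > 0) {
    rng <- local({
      set.seed(seed)
      matrix(stats::rnorm(length(resp), sd = noise_sd), nrow = nrow(resp))
    })
    resp <- resp + rng
  }
  colnames(resp) <- format(concentrations, scientific = TRUE, digits = 6)
  structure(list(time = time, t_assoc = t_assoc,
                 concentrations = concentrations, responses = resp,
                 noise_sd = noise_sd,
                 truth = list(kon = kon, koff = koff, rmax = rmax,
                              kd = koff / kon)),
            class = "SensorgramSet")
}

#' @export
print.SensorgramSet <- function(x, ...) {
  cat(sprintf("SensorgramSet: %d traces (%.3g-%.3g M), %d points, t_assoc %gs, noise SD %g\n",
              length(x$concentrations), min(x$concentrations),
              max(x$concentrations), length(x$time), x$t_assoc, x$noise_sd))
  invisible(x)
}

#' Write / read sensorgram CSV
#'
#' Format: a \code{time} column plus one response column per concentration,
#' named by the molar concentration.
#'
#' @param data A \code{SensorgramSet}.
#' @param path CSV file.
#' @export
write_sensorgrams <- function(data, path) {
  df <- data.frame(time = data$time, data$responses, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  # phase boundary carried in a comment-free sidecar column name is fragile;
  # store it as an attribute row instead
  invisible(path)
}

#' @rdname write_sensorgrams
#' @param t_assoc Association phase length (seconds) of the stored data.
#' @export
read_sensorgrams <- function(path, t_assoc) {
  df <- utils::read.csv(path, check.names = FALSE)
  structure(list(time = df$time, t_assoc = t_assoc,
                 concentrations = as.numeric(names(df)[-1]),
                 responses = as.matrix(df[, -1, drop = FALSE]),
                 noise_sd = NA_real_, truth = NULL),
            class = "SensorgramSet")
}

fit_residuals <- function(par, data) {
  kon <- exp(par[1]); koff <- exp(par[2]); rmax <- exp(par[3])
  pred <- vapply(data$concentrations, function(cc)
    response_1to1(data$time, cc, kon, koff, rmax, data$t_assoc),
    numeric(length(data$time)))
  as.numeric(pred - data$responses)
}

#' Fit the 1:1 Langmuir model to a sensorgram set
#'
#' Nonlinear least squares over both phases with multi-start
#' initialization (Levenberg-Marquardt via minpack.lm). Global mode shares
#' kon/koff/Rmax across all traces (the default, matching common
#' instrument practice); per-trace mode fits each concentration separately
#' for diagnostics.
#'
#' @param data A \code{SensorgramSet}.
#' @param mode \code{"global"} or \code{"per_trace"}.
#' @return A \code{KineticsFit}: \code{kon}, \code{koff}, \code{kd},
#'   \code{rmax}, \code{residual_rms} per trace, \code{fit_mode}; in
#'   per-trace mode the parameters are per-trace vectors.
#' @export
fit_1to1 <- function(data, mode = c("global", "per_trace")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "SensorgramSet"))
  if (mode == "global" && length(data$concentrations) < 2L)
    stop("global mode needs at least 2 concentrations", call. = FALSE)

  fit_one <- function(subset_data) {
    rmax0 <- max(subset_data$responses, 1e-6)
    starts <- expand.grid(kon = c(1e4, 1e5, 1e6),
                          koff = c(1e-4, 1e-3, 1e-2))
    best <- NULL; diagnostics <- character(0)
    for (s in seq_len(nrow(starts))) {
      par0 <- log(c(starts$kon[s], starts$koff[s], rmax0))
      ans <- tryCatch(
        minpack.lm::nls.lm(par0, fn = fit_residuals, data = subset_data,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
        error = function(e) e)
      if (inherits(ans, "error")) {
        diagnostics <- c(diagnostics, conditionMessage(ans))
        next
      }
      if (is.null(best) || ans$deviance < best$deviance) best <- ans
    }
    if (is.null(best))
      stop("1:1 fit did not converge from any start; diagnostics: ",
           paste(unique(diagnostics), collapse = "; "), call. = FALSE)
    best
  }

  trace_rms <- function(fit, d) {
    res <- matrix(fit_residuals(fit$par, d), ncol = length(d$concentrations))
    sqrt(colMeans(res^2))
  }

  if (mode == "global") {
    best <- fit_one(data)
    kon <- exp(best$par[1]); koff <- exp(best$par[2]); rmax <- exp(best$par[3])
    rms <- trace_rms(best, data)
  } else {
    kon <- koff <- rmax <- rms <- numeric(length(data$concentrations))
    for (i in seq_along(data$concentrations)) {
      d <- data
      d$concentrations <- data$concentrations[i]
      d$responses <- data$responses[, i, drop = FALSE]
      best <- fit_one(d)
      kon[i] <- exp(best$par[1]); koff[i] <- exp(best$par[2])
      rmax[i] <- exp(best$par[3])
      rms[i] <- trace_rms(best, d)
    }
  }
  structure(list(kon = kon, koff = koff, kd = koff / kon, rmax = rmax,
                 residual_rms = rms, fit_mode = mode),
            class = "KineticsFit")
}

#' @export
print.KineticsFit <- function(x, ...) {
  cat(sprintf("KineticsFit (%s): kon %.4g /M/s, koff %.4g /s, KD %.4g M (%.3g nM); RMS %.3g\n",
              x$fit_mode, x$kon[1], x$koff[1], x$kd[1], 1e9 * x$kd[1],
              mean(x$residual_rms)))
  invisible(x)
}

# four-parameter logistic
fourpl <- function(conc, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / conc)^hill)
}

#' Simulate a titration curve
#'
#' 4PL response over a concentration series with optional proportional
#' Gaussian noise, deterministic given the seed.
#'
#' @param concentrations Molar concentrations.
#' @param ec50 True EC50 (molar).
#' @param top,bottom Response asymptotes.
#' @param hill Hill slope.
#' @param noise_frac Noise SD as a fraction of the response span.
#' @param seed Integer seed.
#' @return Data frame \code{concentration}, \code{response}.
#' @export
simulate_titration <- function(concentrations, ec50, top = 1, bottom = 0,
                               hill = 1, noise_frac = 0, seed = 1) {
  stopifnot(ec50 > 0, top > bottom)
  r <- fourpl(concentrations, bottom, top, ec50, hill)
  if (noise_frac > 0) {
    set.seed(seed)
    r <- r + stats::rnorm(length(r), sd = noise_frac * (top - bottom))
  }
  data.frame(concentration = concentrations, response = r)
}

#' Fit a four-parameter logistic titration (EC50)
#'
#' @param concentrations Molar concentrations (>= 5 points spanning the
#'   inflection).
#' @param responses Responses at those concentrations.
#' @return An \code{Ec50Fit}: \code{ec50} (input concentration scale),
#'   \code{hill}, \code{top}, \code{bottom}, \code{residual_rms}.
#' @export
fit_ec50 <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses))
  if (length(concentrations) < 5L)
    stop("need at least 5 concentration points", call. = FALSE)
  span <- diff(range(responses))
  if (span < 1e-12 * max(abs(responses), 1) || span == 0)
    stop("no dose-dependence: responses are flat", call. = FALSE)
  ord <- order(concentrations)
  concentrations <- concentrations[ord]; responses <- responses[ord]
  # starts from the data: EC50 near the half-maximal crossing
  half <- (min(responses) + max(responses)) / 2
  ec50_0 <- concentrations[which.min(abs(responses - half))]
  resid_fn <- function(par) {
    fourpl(concentrations, par[1], par[1] + exp(par[2]), exp(par[3]),
           exp(par[4])) - responses
  }
  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    par0 <- c(min(responses), log(max(span, 1e-9)), log(ec50_0), log(h0))
    ans <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(ans) && (is.null(best) || ans$deviance < best$deviance))
      best <- ans
  }
  if (is.null(best)) stop("EC50 fit did not converge", call. = FALSE)
  p <- best$par
  if (!is.finite(exp(p[3])) || exp(p[2]) <= 0)
    stop("no dose-dependence: degenerate 4PL fit", call. = FALSE)
  structure(list(ec50 = exp(p[3]), hill = exp(p[4]),
                 top = p[1] + exp(p[2]), bottom = p[1],
                 residual_rms = sqrt(best$deviance / length(responses))),
            class = "Ec50Fit")
}

#' @export
print.Ec50Fit <- function(x, ...) {
  cat(sprintf("Ec50Fit: EC50 %.4g, Hill %.3g, span [%.3g, %.3g], RMS %.3g\n",
              x$ec50, x$hill, x$bottom, x$top, x$residual_rms))
  invisible(x)
}

#' Write a kinetics or EC50 fit as JSON
#'
#' @param fit A \code{KineticsFit} or \code{Ec50Fit}.
#' @param path Output file.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
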