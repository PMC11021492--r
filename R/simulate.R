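#' Parameters for a synthetic twist-relaxation trajectory
#'
#' Emulates the relaxation of a flat ribbon to its equilibrium twist as
#' seen in replicate simulations: a saturating-exponential approach to the
#' plateau, decorated with mean-reverting (Ornstein-Uhlenbeck) fluctuations
#' whose stationary standard deviation is controlled. The defaults reach
#' > 98% of the plateau by 20 ns.
#'
#' @param theta_eq Plateau twist, degrees (default 98).
#' @param tau Relaxation time, ns (default 5).
#' @param sigma Stationary fluctuation sd, degrees (default 3).
#' @param tau_noise Correlation time of the fluctuations, ns (default 1):
#'   thermal twist fluctuations decorrelate much faster than the
#'   structural relaxation itself.
#' @param t_total Total simulated time, ns (default 100).
#' @param dt Time step, ns (default 0.2).
#' @param n_runs Number of independent replicate runs (default 4).
#' @param seed Integer seed; every run draws from a stream derived from it.
#' @return A list of class `"relaxation_params"`.
#' @export
relaxation_params <- function(theta_eq = 98, tau = 5, sigma = 3,
                              tau_noise = 1, t_total = 100, dt = 0.2,
                              n_runs = 4L, seed = 1L) {
  check_number(theta_eq, "theta_eq")
  check_number(tau, "tau", lower = 0, allow_lower = FALSE)
  check_number(sigma, "sigma", lower = 0)
  check_number(tau_noise, "tau_noise", lower = 0, allow_lower = FALSE)
  check_number(dt, "dt", lower = 0, allow_lower = FALSE)
  check_number(t_total, "t_total", lower = dt)
  n_runs <- check_count(n_runs, "n_runs", lower = 1L)
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  structure(
    list(theta_eq = theta_eq, tau = tau, sigma = sigma,
         tau_noise = tau_noise, t_total = t_total, dt = dt,
         n_runs = n_runs, seed = seed),
    class = "relaxation_params"
  )
}

#' Simulate a multi-run twist relaxation time series
#'
#' Per run r, \eqn{\theta_r(t) = \theta_{eq}(1 - e^{-t/\tau}) + x_r(t)}
#' with \eqn{x_r} a discrete Ornstein-Uhlenbeck process of correlation time
#' `tau_noise` and stationary sd `sigma`, seeded reproducibly per run.
#'
#' @param params A [relaxation_params()] object.
#' @return A tibble of class `"twist_profile"` with columns `run`, `frame`,
#'   `time` (ns), `theta_deg`; per-time replicate mean/sd in
#'   `attr(, "summary")`.
#' @export
#' @examples
#' ts <- simulate_twist_relaxation(relaxation_params(seed = 7))
#' head(attr(ts, "summary"))
simulate_twist_relaxation <- function(params = relaxation_params()) {
  stopifnot(inherits(params, "relaxation_params"))
  t <- seq(params$dt, params$t_total, by = params$dt)
  det <- params$theta_eq * (1 - exp(-t / params$tau))
  a <- exp(-params$dt / params$tau_noise)
  innov_sd <- params$sigma * sqrt(1 - a^2)
  runs <- purrr::map(seq_len(params$n_runs), function(r) {
    with_seed_or_not(derive_seed(params$seed, r), {
      x <- numeric(length(t))
      if (params$sigma > 0) {
        z <- stats::rnorm(length(t))
        # the ribbon starts flat and unperturbed: x(0) = 0
        x[1] <- innov_sd * z[1]
        for (k in seq_along(t)[-1]) x[k] <- a * x[k - 1] + innov_sd * z[k]
      }
      tibble::tibble(run = r, frame = seq_along(t), time = t,
                     theta_deg = det + x)
    })
  })
  series <- dplyr::bind_rows(runs)
  summary <- dplyr::summarise(
    dplyr::group_by(series, .data$frame, .data$time),
    mean_theta = mean(.data$theta_deg),
    sd_theta = if (params$n_runs > 1) stats::sd(.data$theta_deg) else NA_real_,
    n_runs = params$n_runs,
    .groups = "drop"
  )
  structure(series, class = c("twist_profile", class(series)),
            summary = summary, params = params,
            single_run = params$n_runs == 1L)
}

# independent per-run streams derived from one base seed (kept within
# 32-bit integer range)
derive_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 1009 + r * 7919) %% 2147483647)
}

#' Fit a saturating-exponential relaxation model
#'
#' Fits \eqn{\theta(t) = \theta_{eq}(1 - e^{-t/\tau})} to a relaxation
#' series (pooled over runs) by nonlinear least squares.
#'
#' @param series A twist-profile tibble with columns `time`, `theta_deg`.
#' @return An object of class `"relaxation_fit"` wrapping the `nls` fit;
#'   supports [generics::tidy()] and [generics::glance()].
#' @export
fit_relaxation <- function(series) {
  if (!all(c("time", "theta_deg") %in% names(series))) {
    abort_bad_arg("`series` needs columns `time` and `theta_deg`.")
  }
  df <- data.frame(t = series$time, y = series$theta_deg)
  # explicit starts: plateau from the tail, tau from the 63.2% crossing
  a0 <- mean(df$y[df$t >= stats::quantile(df$t, 0.8)])
  tau0 <- stats::approx(cummax(df$y[order(df$t)]) / a0,
                        sort(df$t), xout = 0.632, ties = "ordered")$y
  if (!is.finite(tau0)) tau0 <- max(df$t) / 5
  # scaleOffset makes the convergence test valid for (near-)zero-residual
  # data, e.g. a noise-free series
  fit <- stats::nls(y ~ A * (1 - exp(-t / tau)), data = df,
                    start = list(A = a0, tau = tau0),
                    control = stats::nls.control(maxiter = 200,
                                                 scaleOffset = 1))
  cf <- stats::coef(fit)
  structure(
    list(fit = fit, theta_eq = unname(cf[["A"]]),
         tau = unname(cf[["tau"]])),
    class = "relaxation_fit"
  )
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf("<relaxation fit> theta_eq = %.2f deg, tau = %.3f ns\n",
              x$theta_eq, x$tau))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.relaxation_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("theta_eq", "tau"),
    estimate = c(x$theta_eq, x$tau),
    std.error = c(sm["A", "Std. Error"], sm["tau", "Std. Error"])
  )
}

#' @export
glance.relaxation_fit <- function(x, ...) {
  r <- stats::residuals(x$fit)
  tibble::tibble(
    sigma = stats::sigma(x$fit),
    df.residual = stats::df.residual(x$fit),
    nobs = length(r),
    deviance = sum(r^2)
  )
}
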