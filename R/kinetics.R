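#' Parameters of the dissolution--hydrolysis cascade
#'
#' Bundles the kinetic constants of the sequential first-order scheme used
#' to model aconitum alkaloids during decoction:
#' \deqn{M \xrightarrow{k_d} A \xrightarrow{k_1} B \xrightarrow{k_2} C}
#' where `M` is undissolved material, `A` the dissolved diester-type
#' (toxic) alkaloid, `B` the monoester-type (bioactive) alkaloid and `C`
#' the aminoalcohol-type end product.  The 30-minute soak that precedes
#' heating is collapsed into `f0`, the fraction of the pool already
#' dissolved when heating starts (t = 0).
#'
#' `inhibition` expresses the hydrolysis-suppressing effect of the
#' co-decoction matrix on the monoester step: the effective rate is
#' `k2 / inhibition`, so values above 1 slow monoester breakdown and
#' preserve `B`.
#'
#' @param M0 Total pool size (arbitrary concentration units, >= 0).
#' @param k_d Dissolution rate, per minute (>= 0).
#' @param k1 Diester -> monoester hydrolysis rate, per minute (>= 0).
#' @param k2 Monoester -> aminoalcohol hydrolysis rate, per minute (>= 0).
#' @param f0 Fraction of `M0` dissolved at t = 0 (in \[0, 1\]).
#' @param inhibition Co-decoction modifier (> 0) dividing `k2`.
#'
#' @return An object of class `cascade_params`.
#' @export
#' @examples
#' cascade_params(M0 = 100, k_d = 0.08, k1 = 0.02, k2 = 0.01)
cascade_params <- function(M0, k_d, k1, k2, f0 = 0.15, inhibition = 1) {
  for (nm in c("M0", "k_d", "k1", "k2", "f0", "inhibition")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(paste0("`", nm, "` must be a single finite number."),
            class = "decoctr_parameter_error")
    }
  }
  if (M0 < 0 || k_d < 0 || k1 < 0 || k2 < 0) {
    abort("Pool size and rates must be non-negative.",
          class = "decoctr_parameter_error")
  }
  if (f0 < 0 || f0 > 1) {
    abort("`f0` must lie in [0, 1].", class = "decoctr_parameter_error")
  }
  if (inhibition <= 0) {
    abort("`inhibition` must be > 0.", class = "decoctr_parameter_error")
  }
  structure(list(M0 = M0, k_d = k_d, k1 = k1, k2 = k2, f0 = f0,
                 inhibition = inhibition),
            class = "cascade_params")
}

#' @export
print.cascade_params <- function(x, ...) {
  cat("<cascade_params> M0 =", x$M0, " k_d =", x$k_d, " k1 =", x$k1,
      " k2 =", x$k2, " f0 =", x$f0, " inhibition =", x$inhibition, "\n")
  invisible(x)
}

# Bateman contribution: amount in compartment `j` of a linear chain at time
# `t`, given a unit amount in compartment `i` at t = 0.  `rates[i:j]` are the
# first-order decay rates of compartments i..j and must be pairwise distinct.
bateman_term <- function(rates, i, j, t) {
  if (i == j) return(exp(-rates[j] * t))
  lam <- rates[i:j]
  out <- numeric(length(t))
  for (l in seq_along(lam)) {
    denom <- prod(lam[-l] - lam[l])
    out <- out + exp(-lam[l] * t) / denom
  }
  prod(lam[-length(lam)]) * out
}

has_rate_ties <- function(rates) {
  if (length(rates) < 2L) return(FALSE)
  d <- abs(outer(rates, rates, "-"))
  scale <- pmax(abs(outer(rates, rates, pmax)), 1e-12)
  any((d / scale)[upper.tri(d)] < 1e-7)
}

# Closed-form chain solution for pairwise-distinct rates: matrix with one
# column per compartment.  `rates[k]` is the decay rate of compartment k;
# material leaving the last compartment is lost to an (untracked) sink.
chain_closed <- function(rates, init, t) {
  n <- length(rates)
  out <- matrix(0, nrow = length(t), ncol = n)
  for (i in seq_len(n)) {
    if (init[i] == 0) next
    for (j in i:n) {
      out[, j] <- out[, j] + init[i] * bateman_term(rates, i, j, t)
    }
  }
  out
}

chain_numeric <- function(rates, init, t) {
  times <- t
  prepend <- times[1] > 0
  if (prepend) times <- c(0, times)
  # chain derivative: dy_k = r_{k-1} y_{k-1} - r_k y_k
  deriv <- function(time, y, parms) {
    inflow <- c(0, parms[-length(parms)] * y[-length(y)])
    list(inflow - parms * y)
  }
  sol <- deSolve::ode(y = init, times = times, func = deriv, parms = rates,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  m <- unname(sol[, -1, drop = FALSE])
  if (prepend) m <- m[-1, , drop = FALSE]
  m
}

chain_solve <- function(rates, init, t, method = c("auto", "closed", "numeric")) {
  method <- match.arg(method)
  ties <- has_rate_ties(rates)
  if (method == "closed" && ties) {
    abort("Closed-form chain solution requires pairwise-distinct rates.",
          class = "decoctr_parameter_error")
  }
  # long chains with close rates are ill-conditioned in the Bateman sums
  if (method == "numeric" || (method == "auto" && (ties || length(rates) > 4))) {
    chain_numeric(rates, init, t)
  } else {
    chain_closed(rates, init, t)
  }
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 1L || anyNA(grid)) {
    abort("`grid` must be a non-empty numeric vector of times in minutes.",
          class = "decoctr_parameter_error")
  }
  if (any(grid < 0) || is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be strictly increasing and non-negative.",
          class = "decoctr_parameter_error")
  }
  grid
}

#' Simulate the dissolution--hydrolysis cascade
#'
#' Solves \eqn{dM/dt = -k_d M}, \eqn{dA/dt = k_d M - k_1 A},
#' \eqn{dB/dt = k_1 A - k_2 B}, \eqn{dC/dt = k_2 B} on a time grid.  When all
#' rates are pairwise distinct the Bateman closed form is used; the degenerate
#' `k1 == k2` case with a fully dissolved pool (`f0 = 1`) uses the
#' \eqn{t e^{-kt}} closed form; any other rate tie falls back to a stiff ODE
#' integrator.  `C` is obtained by mass conservation in the closed-form path,
#' so `M + A + B + C = M0` holds exactly.
#'
#' @param params A [cascade_params()] object.
#' @param grid Strictly increasing vector of times in minutes.
#' @param init Optional named vector `c(M=, A=, B=, C=)` overriding the
#'   default split `M(0) = (1 - f0) M0`, `A(0) = f0 M0`, `B(0) = C(0) = 0`.
#' @param method `"auto"` (default), `"closed"` or `"numeric"`.
#'
#' @return A tibble with columns `time_min`, `M`, `A`, `B`, `C`; the input
#'   parameters are attached as attribute `"params"`.
#' @export
#' @examples
#' p <- cascade_params(M0 = 100, k_d = 0.08, k1 = 0.02, k2 = 0.01)
#' tr <- simulate_cascade(p, seq(0, 240, by = 1))
#' max(abs(tr$M + tr$A + tr$B + tr$C - 100))
simulate_cascade <- function(params, grid, init = NULL,
                             method = c("auto", "closed", "numeric")) {
  stopifnot(inherits(params, "cascade_params"))
  method <- match.arg(method)
  grid <- check_grid(grid)
  k2_eff <- params$k2 / params$inhibition
  if (is.null(init)) {
    init <- c(M = (1 - params$f0) * params$M0, A = params$f0 * params$M0,
              B = 0, C = 0)
  } else {
    if (!all(c("M", "A", "B", "C") %in% names(init))) {
      abort("`init` must have entries M, A, B, C.",
            class = "decoctr_parameter_error")
    }
    init <- init[c("M", "A", "B", "C")]
  }
  total <- sum(init)
  rates3 <- c(params$k_d, params$k1, k2_eff)
  ties <- has_rate_ties(rates3)
  degenerate_pair <- ties && init[["M"]] == 0 &&
    abs(params$k1 - k2_eff) <= 1e-7 * max(params$k1, k2_eff, 1e-12) &&
    !has_rate_ties(c(params$k_d, params$k1))

  if (params$k1 == 0 && method != "numeric") {
    # no diester hydrolysis: the chain truncates at A and B only decays
    M <- init[["M"]] * exp(-params$k_d * grid)
    A <- init[["A"]] + init[["M"]] - M
    if (params$k_d == 0) { M <- rep(init[["M"]], length(grid)); A <- rep(init[["A"]], length(grid)) }
    B <- init[["B"]] * exp(-k2_eff * grid)
    C <- total - M - A - B
  } else if (!ties && method != "numeric") {
    sol <- chain_closed(rates3, unname(init[c("M", "A", "B")]), grid)
    M <- sol[, 1]; A <- sol[, 2]; B <- sol[, 3]
    C <- total - M - A - B
  } else if (degenerate_pair && method != "numeric") {
    # k1 == k2 with nothing left to dissolve: B picks up the t*exp(-kt) term
    k <- params$k1
    M <- rep(0, length(grid))
    A <- init[["A"]] * exp(-k * grid)
    B <- init[["B"]] * exp(-k2_eff * grid) + init[["A"]] * k * grid * exp(-k * grid)
    C <- total - M - A - B
  } else {
    if (method == "closed") {
      abort("Closed-form cascade requires pairwise-distinct rates (or the k1 == k2, f0 = 1 special case).",
            class = "decoctr_parameter_error")
    }
    sol <- chain_numeric(c(rates3, 0), unname(init), grid)
    M <- sol[, 1]; A <- sol[, 2]; B <- sol[, 3]; C <- sol[, 4]
  }
  out <- tibble(time_min = grid, M = M, A = A, B = B, C = pmax(C, 0))
  attr(out, "params") <- params
  out
}

#' Simulate a biphasic reaction intermediate
#'
#' Models a species that is produced from a finite source pool and consumed
#' downstream (e.g. pentagalloylglucose during peony decoction, formed by
#' hydrolysis of higher galloylglucoses and further hydrolysed to gallic
#' acid).  With a finite source and `consume_rate > 0` the trace rises and
#' then falls with a single interior maximum.  A finite `release_rate`
#' inserts an upstream release step (source material must itself be freed
#' from the herb matrix first), which delays the rise into the sigmoidal
#' slow-then-fast shape seen for tannin intermediates.
#'
#' @param rise_rate Formation rate from the source pool, per minute (>= 0).
#' @param consume_rate Downstream consumption rate, per minute (>= 0).
#' @param source_pool Total source amount (>= 0).
#' @param grid Strictly increasing times in minutes.
#' @param release_rate Upstream release rate(s), per minute; `Inf` (default)
#'   makes the whole pool available immediately.  A vector describes a
#'   multi-stage release cascade (progressive hydrolysis of higher
#'   galloylglucoses), each stage adding delay and sharpening the late rise.
#' @param initial Intermediate amount already present at t = 0.
#'
#' @return Tibble with columns `time_min`, `value`.
#' @export
simulate_biphasic_intermediate <- function(rise_rate, consume_rate,
                                           source_pool, grid,
                                           release_rate = Inf, initial = 0) {
  if (rise_rate < 0 || consume_rate < 0 || source_pool < 0 || initial < 0 ||
      any(!is.infinite(release_rate) & release_rate < 0)) {
    abort("Rates, pool and initial amount must be non-negative.",
          class = "decoctr_parameter_error")
  }
  grid <- check_grid(grid)
  release_rate <- release_rate[is.finite(release_rate)]
  rates <- c(release_rate, rise_rate, consume_rate)
  init <- c(source_pool, rep(0, length(rates) - 2), initial)
  sol <- chain_solve(rates, init, grid)
  tibble(time_min = grid, value = pmax(sol[, length(rates)], 0))
}

#' Simulate a thermal conversion pair
#'
#' Precursor/product pair under heat-driven conversion (gingerols to
#' shogaols and zingerone during ginger decoction).  The precursor dissolves
#' from the herb matrix and converts with first-order rate `conversion_rate`;
#' the product accumulates.  In a co-decoction system the matrix suppresses
#' conversion, expressed as `conversion_rate / inhibition`.
#'
#' @param precursor_params [cascade_params()] describing the precursor pool
#'   (`M0`, `k_d`, `f0` are used; its `k1`, `k2` are ignored).
#' @param conversion_rate Precursor -> product rate, per minute (>= 0).
#' @param grid Strictly increasing times in minutes.
#' @param product0 Product amount already present at t = 0.
#' @param inhibition Modifier (> 0) dividing `conversion_rate`.
#'
#' @return Tibble with columns `time_min`, `precursor`, `product`.  When
#'   dissolution is complete (`f0 = 1`) and only conversion acts,
#'   `precursor + product` is conserved.
#' @export
simulate_conversion_pair <- function(precursor_params, conversion_rate, grid,
                                     product0 = 0, inhibition = 1) {
  stopifnot(inherits(precursor_params, "cascade_params"))
  if (conversion_rate < 0 || product0 < 0) {
    abort("`conversion_rate` and `product0` must be non-negative.",
          class = "decoctr_parameter_error")
  }
  if (inhibition <= 0) {
    abort("`inhibition` must be > 0.", class = "decoctr_parameter_error")
  }
  grid <- check_grid(grid)
  p <- precursor_params
  kc <- conversion_rate / inhibition
  init <- c((1 - p$f0) * p$M0, p$f0 * p$M0)
  sol <- chain_solve(c(p$k_d, kc), init, grid)
  M <- sol[, 1]; P <- sol[, 2]
  Q <- product0 + (p$M0 - M - P)
  tibble(time_min = grid, precursor = P, product = Q)
}

#' Simulate a dissolution-only (stable) compound
#'
#' Compounds such as atractylenolides, fuzitine and songorine dissolve early
#' and then stay flat: \eqn{v(t) = M_0 (1 - (1 - f_0) e^{-k_d t})}, a
#' monotone non-decreasing trace approaching the plateau `M0`.
#'
#' @param M0 Plateau amount (>= 0).
#' @param k_d Dissolution rate, per minute (>= 0).
#' @param grid Strictly increasing times in minutes.
#' @param f0 Fraction dissolved at t = 0.
#'
#' @return Tibble with columns `time_min`, `value`.
#' @export
simulate_stable <- function(M0, k_d, grid, f0 = 0.15) {
  if (M0 < 0 || k_d < 0) {
    abort("`M0` and `k_d` must be non-negative.",
          class = "decoctr_parameter_error")
  }
  if (f0 < 0 || f0 > 1) {
    abort("`f0` must lie in [0, 1].", class = "decoctr_parameter_error")
  }
  grid <- check_grid(grid)
  tibble(time_min = grid, value = M0 * (1 - (1 - f0) * exp(-k_d * grid)))
}

#' Recover hydrolysis rates from a noiseless monoester trace
#'
#' Least-squares refit of `k1` and `k2` against an observed monoester (`B`)
#' trace, holding the dissolution parameters fixed.  Used to verify that the
#' cascade is identifiable from its own output.
#'
#' @param trace Tibble with `time_min` and `value` (the B compartment).
#' @param params [cascade_params()] holding the true `M0`, `k_d`, `f0`;
#'   its `k1`, `k2` seed the optimisation start (perturbed internally).
#' @param start Optional numeric `c(k1=, k2=)` starting values.
#'
#' @return Named numeric vector `c(k1 =, k2 =)`.
#' @export
recover_cascade_rates <- function(trace, params, start = NULL) {
  stopifnot(inherits(params, "cascade_params"))
  if (is.null(start)) start <- c(k1 = params$k1 * 1.4, k2 = params$k2 * 0.7)
  obj <- function(theta) {
    k1 <- exp(theta[1]); k2 <- exp(theta[2])
    if (!is.finite(k1) || !is.finite(k2) || k1 > 10 || k2 > 10) {
      return(1e12)
    }
    p <- cascade_params(params$M0, params$k_d, k1, k2, params$f0)
    sim <- simulate_cascade(p, trace$time_min)
    sum((sim$B - trace$value)^2)
  }
  fit <- optim(log(pmax(start, 1e-8)), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  setNames(exp(fit$par), c("k1", "k2"))
}
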