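#' Two-compartment C-peptide kinetic parameters
#'
#' Population C-peptide kinetics from the standard anthropometric
#' regression (Van Cauter et al.): the biexponential disappearance curve is
#' described by a short and a long half-life and the fraction associated
#' with the short component, mapped here to the rate constants of a
#' two-compartment model with irreversible loss from the central
#' (plasma) compartment.
#'
#' The kinetic constants are population-derived, never fitted per subject:
#' the diabetic class uses the type 2 diabetes coefficients, the
#' non-diabetic class the normal coefficients; the long half-life increases
#' with age and the distribution volume with body surface area. `sex` is
#' accepted for interface completeness and auditability but does not enter
#' the regression (it acts only through body surface area).
#'
#' @param age Age, years (10-100).
#' @param sex `"M"` or `"F"`.
#' @param bsa Body surface area, m^2 (1-3).
#' @param diabetic Logical; selects the diabetic population class.
#' @return An object of class `cp_kinetics` with fields `k01` (irreversible
#'   loss, 1/min), `k12`, `k21` (exchange rates, 1/min), `volume` (central
#'   distribution volume, litres), and the underlying `half_short`,
#'   `half_long` (min) and `fraction`.
#' @export
kinetic_parameters <- function(age, sex = c("M", "F"), bsa,
                               diabetic = TRUE) {
  sex <- match.arg(sex)
  if (!is.finite(age) || age < 10 || age > 100)
    stop("age must be within [10, 100] years", call. = FALSE)
  if (!is.finite(bsa) || bsa < 1 || bsa > 3)
    stop("body surface area must be within [1, 3] m^2", call. = FALSE)
  if (diabetic) {
    half_short <- 4.52; fraction <- 0.78
  } else {
    half_short <- 4.95; fraction <- 0.76
  }
  half_long <- 0.14 * age + 29.2
  volume <- 1.92 * bsa + 0.64
  a <- log(2) / half_short   # fast exponent, 1/min
  b <- log(2) / half_long    # slow exponent, 1/min
  f <- fraction
  # biexponential impulse response F e^{-at} + (1-F) e^{-bt} in the central
  # compartment maps to rates via a+b = k01+k12+k21, ab = k01 k12 and
  # C1'(0) = -(k01+k21) = -(Fa + (1-F)b)
  k12 <- (1 - f) * a + f * b
  k01 <- a * b / k12
  k21 <- f * a + (1 - f) * b - k01
  x <- structure(list(k01 = k01, k12 = k12, k21 = k21, volume = volume,
                      half_short = half_short, half_long = half_long,
                      fraction = fraction),
                 class = "cp_kinetics")
  stopifnot(k01 > 0, k12 > 0, k21 > 0, volume > 0)
  x
}

#' @export
print.cp_kinetics <- function(x, ...) {
  cat(sprintf(paste0("<cp_kinetics> k01 %.4f, k12 %.4f, k21 %.4f 1/min; ",
                     "V %.2f l (t1/2 %.2f / %.1f min)\n"),
              x$k01, x$k12, x$k21, x$volume, x$half_short, x$half_long))
  invisible(x)
}

# One-step propagation matrices for the two-compartment system
#   dC1/dt = -(k01+k21) C1 + k12 C2 + u(t)
#   dC2/dt =  k21 C1 - k12 C2
# with u(t) linear on the step. Returns E (2x2) and vectors m0, m1 such
# that x(h) = E x(0) + m0 u(0) + m1 u(h); exact for linear forcing, so the
# grid solution is reproducible bit-for-bit at a fixed step.
cp_step_matrices <- function(kinetics, h) {
  A <- matrix(c(-(kinetics$k01 + kinetics$k21), kinetics$k12,
                kinetics$k21, -kinetics$k12), 2, 2, byrow = TRUE)
  eg <- eigen(A)
  E <- Re(eg$vectors %*% diag(exp(eg$values * h)) %*% solve(eg$vectors))
  Ainv <- solve(A)
  I2 <- diag(2)
  psi0 <- Ainv %*% (E - I2)                 # int_0^h e^{A s} ds
  psi1 <- E %*% (h * Ainv - Ainv %*% Ainv) + Ainv %*% Ainv  # int s e^{A s} ds
  b <- c(1, 0)
  list(E = E, m0 = as.numeric((psi1 / h) %*% b),
       m1 = as.numeric((psi0 - psi1 / h) %*% b))
}

#' Simulate plasma C-peptide from a secretion trajectory
#'
#' Forward two-compartment model: integrates the kinetic equations driven
#' by an insulin secretion rate given on a time grid, assuming the
#' secretion rate is linear between grid nodes (the update on each step is
#' the exact matrix-exponential solution for linear forcing). Both
#' compartments start at the steady state consistent with the initial
#' plasma concentration `c0`.
#'
#' @param times Grid times, minutes, strictly increasing, step <= 5 min.
#' @param isr Insulin secretion rate at each grid time, pmol min^-1 m^-2,
#'   non-negative.
#' @param kinetics A [kinetic_parameters()] object.
#' @param bsa Body surface area, m^2.
#' @param c0 Plasma C-peptide at `times[1]`, nmol/l.
#' @return Plasma C-peptide concentration on `times`, nmol/l.
#' @export
simulate_cpeptide <- function(times, isr, kinetics, bsa, c0 = 0) {
  stopifnot(length(times) == length(isr), length(times) >= 2)
  if (any(!is.finite(isr)) || any(isr < 0))
    stop("secretion rates must be finite and non-negative", call. = FALSE)
  if (c0 < 0) stop("initial concentration must be non-negative", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(dt > 5 + 1e-9))
    stop("grid step must be at most 5 min", call. = FALSE)
  # forcing in nmol/l per min: ISR [pmol/min/m^2] * bsa / volume / 1000
  u <- isr * bsa / kinetics$volume / 1000
  x <- c(c0, c0 * kinetics$k21 / kinetics$k12)  # exchange steady state
  out <- numeric(length(times))
  out[1] <- c0
  same <- length(unique(round(dt, 12))) == 1L
  if (same) step <- cp_step_matrices(kinetics, dt[1])
  for (i in seq_along(dt)) {
    if (!same) step <- cp_step_matrices(kinetics, dt[i])
    x <- as.numeric(step$E %*% x) + step$m0 * u[i] + step$m1 * u[i + 1]
    out[i + 1] <- x[1]
  }
  out
}

# Linear observation map: matrices (H, h0) with
#   C1(times) = H %*% isr_grid + h0 * c0
# for the same discretisation as simulate_cpeptide on a uniform grid.
# Used by the fitter, where the C-peptide prediction must be linear in the
# secretion values.
cp_linear_map <- function(grid, kinetics, bsa, c0) {
  n <- length(grid)
  h <- diff(grid)
  stopifnot(length(unique(round(h, 12))) == 1L)
  step <- cp_step_matrices(kinetics, h[1])
  scale <- bsa / kinetics$volume / 1000
  # state = S %*% u + s0, propagated column-wise
  S <- matrix(0, 2, n)
  s0 <- c(1, kinetics$k21 / kinetics$k12)
  H <- matrix(0, n, n)
  h0 <- numeric(n)
  h0[1] <- 1
  for (i in seq_len(n - 1)) {
    S <- step$E %*% S
    S[, i] <- S[, i] + step$m0 * scale
    S[, i + 1] <- S[, i + 1] + step$m1 * scale
    s0 <- as.numeric(step$E %*% s0)
    H[i + 1, ] <- S[1, ]
    h0[i + 1] <- s0[1]
  }
  list(H = H, h0 = h0)
}
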