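# Seeded generators for every input the pipeline consumes: bisubstrate
# initial-rate grids, single-substrate saturation series, NADH-coupled
# progress curves, and dose-response tables. All generators are pure
# functions of (parameters, seed).

#' Bisubstrate design grid
#'
#' Fully crossed two-substrate design with replication. Labels follow the
#' dataset convention: `a_label` is the substrate stored in column `A`.
#'
#' @param a_levels,b_levels Concentrations (mM) of substrates A and B; all
#'   strictly positive.
#' @param replicates Number of replicate measurements per (A, B) cell.
#' @param a_label,b_label Substrate names.
#' @return An object of class `design_grid`.
#' @examples
#' design_grid(c(0.05, 0.1, 0.25), c(0.025, 0.05, 0.125), replicates = 2)
#' @export
design_grid <- function(a_levels, b_levels, replicates = 2,
                        a_label = "A", b_label = "B") {
  check_conc(a_levels, "a_levels"); check_conc(b_levels, "b_levels")
  if (any(a_levels <= 0) || any(b_levels <= 0))
    stop_bad_arg("design concentrations must be strictly positive")
  if (anyDuplicated(a_levels) || anyDuplicated(b_levels))
    stop_bad_arg("design levels must be distinct")
  replicates <- as.integer(replicates)
  if (replicates < 1) stop_bad_arg("`replicates` must be >= 1")
  structure(list(a_levels = sort(a_levels), b_levels = sort(b_levels),
                 replicates = replicates,
                 a_label = a_label, b_label = b_label),
            class = "design_grid")
}

#' Reference bisubstrate design for SLA dehydrogenase
#'
#' The default two-way initial-rate design used throughout the package for
#' mechanism work on RlGabD: NAD+ at 0.05, 0.1, 0.15 and 0.25 mM fully
#' crossed with D-SLA at 0.0125, 0.025, 0.05, 0.125 and 0.25 mM. All D-SLA
#' levels stay at or below 0.25 mM, the onset of substrate inhibition, so the
#' grid carries clean Bi-Bi information.
#'
#' @param replicates Replicates per cell (default 2, typical duplicate
#'   spectrophotometric assays).
#' @return A [design_grid()] with A = NAD+ and B = D-SLA.
#' @export
reference_bisubstrate_design <- function(replicates = 2) {
  design_grid(a_levels = c(0.05, 0.1, 0.15, 0.25),
              b_levels = c(0.0125, 0.025, 0.05, 0.125, 0.25),
              replicates = replicates,
              a_label = "NAD+", b_label = "D-SLA")
}

#' Noise model for simulated rates
#'
#' @param kind `"none"`, `"constant_sd"` (homoscedastic absolute SD),
#'   `"constant_cv"` (SD proportional to the true rate), or `"mixed"`
#'   (`sd = sqrt((cv*v)^2 + sd_abs^2)`). The package default for realistic
#'   simulations is `mixed` with 5% CV and a 1e-6 rate-unit floor, typical of
#'   spectrophotometric initial-rate scatter.
#' @param sd_abs Absolute SD component (rate units).
#' @param cv Proportional SD component (fraction of the true rate).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "constant_sd", "constant_cv", "mixed"),
                        sd_abs = 0, cv = 0) {
  kind <- match.arg(kind)
  if (sd_abs < 0 || cv < 0) stop_bad_arg("noise magnitudes must be >= 0")
  structure(list(kind = kind, sd_abs = sd_abs, cv = cv),
            class = "noise_model")
}

#' Default realistic assay noise
#'
#' Mixed noise: 5% CV with an absolute floor of 1e-6 rate units.
#' @return A [noise_model()].
#' @export
default_noise <- function() noise_model("mixed", sd_abs = 1e-6, cv = 0.05)

noise_sd <- function(noise, v_true) {
  switch(noise$kind,
    none = rep(0, length(v_true)),
    constant_sd = rep(noise$sd_abs, length(v_true)),
    constant_cv = noise$cv * v_true,
    mixed = sqrt((noise$cv * v_true)^2 + noise$sd_abs^2)
  )
}

new_rate_dataset <- function(df, a_label, b_label, E0 = NULL,
                             provenance = list()) {
  rownames(df) <- NULL
  structure(df,
            a_label = a_label, b_label = b_label, E0 = E0,
            provenance = provenance,
            class = c("rate_dataset", "data.frame"))
}

#' Construct a rate dataset
#'
#' A `rate_dataset` is a data frame of initial-rate records with columns
#' `A`, `B` (concentrations, mM), `v` (rate) and `replicate`, plus substrate
#' labels, optional enzyme concentration and provenance held as attributes.
#'
#' @param A,B Substrate concentrations (mM).
#' @param v Observed initial rates (>= 0).
#' @param replicate Integer replicate ids.
#' @param a_label,b_label Substrate names.
#' @param E0 Optional enzyme concentration (mM).
#' @param provenance List describing where the data came from (generator
#'   parameters and seed, or file source).
#' @return A `rate_dataset`.
#' @export
rate_dataset <- function(A, B, v, replicate = 1L,
                         a_label = "A", b_label = "B", E0 = NULL,
                         provenance = list(source = "constructed")) {
  n <- max(length(A), length(B), length(v))
  df <- data.frame(A = rep_len(A, n), B = rep_len(B, n),
                   v = rep_len(v, n),
                   replicate = as.integer(rep_len(replicate, n)))
  check_conc(df$A, "A"); check_conc(df$B, "B")
  if (any(!is.finite(df$v)) || any(df$v < 0))
    stop_bad_arg("rates must be finite and >= 0")
  key <- paste(df$A, df$B, df$replicate)
  if (anyDuplicated(key))
    stop_bad_arg("duplicate (A, B, replicate) records: ",
                 paste(unique(key[duplicated(key)]), collapse = "; "))
  if (length(unique(df$A)) < 2 && length(unique(df$B)) < 2)
    stop_bad_arg("at least one substrate concentration must vary")
  new_rate_dataset(df, a_label, b_label, E0, provenance)
}

#' @export
print.rate_dataset <- function(x, ...) {
  cat("<rate_dataset> ", nrow(x), " records; A = ", attr(x, "a_label"),
      " (", length(unique(x$A)), " levels), B = ", attr(x, "b_label"),
      " (", length(unique(x$B)), " levels)\n", sep = "")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Simulate bisubstrate initial rates
#'
#' Evaluates the chosen rate law over a crossed design and adds measurement
#' noise; negative draws are clipped to zero (recorded in provenance).
#' Identical (parameters, seed) pairs give identical datasets.
#'
#' @param model [mechanism_model()] used as the generative truth.
#' @param p [kinetic_params()] for that model.
#' @param design [design_grid()].
#' @param noise [noise_model()]; default none.
#' @param seed Integer seed; `NULL` uses (and advances) the session RNG.
#' @return A [rate_dataset()] whose provenance records the generator call.
#' @examples
#' p <- kinetic_params(V = 17.8, Kia = 0.081, Kb = 0.13)
#' d <- generate_initial_rates(mechanism_model("RAPID_EQ_ORDERED"), p,
#'                             reference_bisubstrate_design(), seed = 1)
#' @export
generate_initial_rates <- function(model, p, design,
                                   noise = noise_model("none"), seed = NULL) {
  stopifnot(inherits(model, "mechanism_model"), inherits(design, "design_grid"),
            inherits(noise, "noise_model"))
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      B = design$b_levels, A = design$a_levels)
  v_true <- rate_law(model, grid$A, grid$B, p)
  sd <- noise_sd(noise, v_true)
  v <- with_seed(seed, v_true + stats::rnorm(length(v_true), 0, sd))
  clipped <- sum(v < 0)
  v <- pmax(v, 0)
  df <- data.frame(A = grid$A, B = grid$B, v = v,
                   replicate = as.integer(grid$replicate))
  new_rate_dataset(df,
    a_label = design$a_label, b_label = design$b_label, E0 = p$E0,
    provenance = list(source = "generate_initial_rates",
                      model = model$name,
                      leading_substrate = model$leading_substrate,
                      params = p[!vapply(p, is.null, logical(1))],
                      noise = unclass(noise), seed = seed,
                      n_clipped_to_zero = clipped))
}

#' Closed-form solution of the irreversible Michaelis-Menten progress curve
#'
#' Solves `KM*log(S0/S) + (S0 - S) = Vm*t` for `S(t)` via the Lambert W
#' function: `S(t) = KM * W((S0/KM) * exp((S0 - Vm*t)/KM))`. Used as the
#' analytical cross-check of the ODE integrator.
#'
#' @param t Time (s), vectorized.
#' @param Vm Maximal depletion rate `kcat * E0` (mM/s).
#' @param KM Michaelis constant (mM).
#' @param S0 Initial substrate concentration (mM).
#' @return Substrate concentration at `t` (mM).
#' @export
integrated_mm_substrate <- function(t, Vm, KM, S0) {
  stopifnot(Vm > 0, KM > 0, S0 >= 0)
  arg <- (S0 / KM) * exp((S0 - Vm * t) / KM)
  vapply(arg, function(a) KM * pracma::lambertWp(a), numeric(1))
}

#' Construct a progress curve
#'
#' Time series of 340 nm absorbance with its assay constants. `A340` must be
#' physical: within `[0, eps*path*S_total]` plus the baseline.
#'
#' @param t Time (s), strictly increasing.
#' @param A340 Absorbance at 340 nm.
#' @param eps NAD(P)H extinction coefficient at 340 nm (mM^-1 cm^-1).
#' @param path Cuvette path length (cm).
#' @param S_total Nominal total substrate (mM), racemate included.
#' @param E0 Optional enzyme concentration (mM).
#' @param baseline Absorbance offset at t = 0.
#' @return An object of class `progress_curve` (a data frame with attributes).
#' @export
progress_curve <- function(t, A340, eps = 6.22, path = 1, S_total,
                           E0 = NULL, baseline = 0) {
  stopifnot(length(t) == length(A340))
  if (any(diff(t) <= 0)) stop_bad_arg("`t` must be strictly increasing")
  if (eps <= 0 || path <= 0 || S_total <= 0)
    stop_bad_arg("`eps`, `path` and `S_total` must be positive")
  amax <- eps * path * S_total + baseline
  if (any(A340 < baseline - 1e-9) || any(A340 > amax * (1 + 1e-9)))
    stop_bad_arg("A340 outside the physical range [baseline, eps*path*S_total + baseline]")
  structure(data.frame(t = t, A340 = A340),
            eps = eps, path = path, S_total = S_total, E0 = E0,
            baseline = baseline,
            class = c("progress_curve", "data.frame"))
}

#' Simulate an NAD(P)H-coupled progress curve
#'
#' Integrates irreversible Michaelis-Menten depletion `dS/dt =
#' -kcat*E0*S/(KM+S)` from `S0 = reactive_fraction * S_total` with a
#' stiff-capable adaptive integrator (lsoda), and converts to absorbance via
#' `A340(t) = eps*path*(S0 - S(t))` assuming 1:1 NAD(P)H:substrate
#' stoichiometry. `reactive_fraction = 0.5` models a racemate of which only
#' one enantiomer is turned over, so the plateau is `eps*path*S_total/2`.
#'
#' @param kcat Turnover number (s^-1).
#' @param KM Michaelis constant (mM).
#' @param E0 Enzyme concentration (mM).
#' @param S_total Nominal total substrate (mM).
#' @param reactive_fraction Fraction of `S_total` the enzyme can consume,
#'   in `[0, 1]`.
#' @param eps,path Assay constants; defaults 6.22 mM^-1 cm^-1 and 1 cm, the
#'   universal NAD(P)H 340 nm values.
#' @param t_end Trace duration (s).
#' @param dt Output sampling interval (s); controls sampling only, not
#'   integration accuracy.
#' @param noise_sd Absorbance noise SD (AU); 0 for a noise-free trace.
#' @param seed Seed for the absorbance noise.
#' @return A [progress_curve()] carrying additional columns `S` (remaining
#'   reactive substrate) and `NADH` (product formed), which conserve mass:
#'   `S + NADH = S0`.
#' @export
generate_progress_curve <- function(kcat, KM, E0, S_total,
                                    reactive_fraction = 1,
                                    eps = 6.22, path = 1,
                                    t_end = 2400, dt = 5,
                                    noise_sd = 0, seed = NULL) {
  if (any(c(kcat, KM, E0, S_total) <= 0))
    stop_bad_arg("kcat, KM, E0, S_total must be positive")
  if (eps <= 0 || path <= 0 || dt <= 0 || t_end <= 0)
    stop_bad_arg("eps, path, t_end, dt must be positive")
  if (reactive_fraction < 0 || reactive_fraction > 1)
    stop_bad_arg("`reactive_fraction` must be in [0, 1]")
  S0 <- reactive_fraction * S_total
  times <- seq(0, t_end, by = dt)
  if (S0 == 0) {
    S <- rep(0, length(times))
  } else {
    sol <- deSolve::ode(
      y = c(S = S0), times = times,
      func = function(t, y, parms) {
        list(-parms$Vm * y[1] / (parms$KM + y[1]))
      },
      parms = list(Vm = kcat * E0, KM = KM),
      method = "lsoda", rtol = 1e-10, atol = 1e-12)
    S <- pmax(as.numeric(sol[, "S"]), 0)
  }
  A <- eps * path * (S0 - S)
  if (noise_sd > 0)
    A <- pmax(0, with_seed(seed, A + stats::rnorm(length(A), 0, noise_sd)))
  pc <- progress_curve(times, pmin(A, eps * path * S_total), eps = eps,
                       path = path, S_total = S_total, E0 = E0)
  pc$S <- S
  pc$NADH <- S0 - S
  attr(pc, "provenance") <- list(source = "generate_progress_curve",
                                 kcat = kcat, KM = KM, E0 = E0,
                                 S_total = S_total,
                                 reactive_fraction = reactive_fraction,
                                 noise_sd = noise_sd, seed = seed)
  pc
}

#' Construct a dose-response table
#'
#' @param I Inhibitor concentrations (uM), >= 0.
#' @param v Observed rates.
#' @param assay Named list of fixed-assay metadata (substrate and cofactor
#'   concentrations); required context for interpreting an IC50.
#' @return An object of class `dose_response` (a data frame with attributes).
#' @export
dose_response <- function(I, v, assay = list()) {
  stopifnot(length(I) == length(v))
  if (any(I < 0)) stop_bad_arg("inhibitor concentrations must be >= 0")
  if (length(unique(I)) < 5)
    stop_bad_arg("at least 5 inhibitor levels are required for IC50 work")
  structure(data.frame(I = I, v = v), assay = assay,
            class = c("dose_response", "data.frame"))
}

#' Simulate an IC50 dose-response experiment
#'
#' `v([I]) = v0 / (1 + ([I]/IC50)^hill)` plus noise, clipped at zero.
#'
#' @param IC50 True half-inhibitory concentration (uM).
#' @param hill Hill coefficient (> 0); 1 for simple binding.
#' @param v0 Uninhibited rate.
#' @param levels Inhibitor concentrations (uM) to measure at.
#' @param noise [noise_model()].
#' @param assay Fixed-assay metadata forwarded to [dose_response()].
#' @param seed Integer seed.
#' @return A [dose_response()].
#' @export
generate_dose_response <- function(IC50, hill = 1, v0,
                                   levels, noise = noise_model("none"),
                                   assay = list(), seed = NULL) {
  if (IC50 <= 0 || hill <= 0 || v0 <= 0)
    stop_bad_arg("IC50, hill and v0 must be positive")
  if (length(levels) == 0) stop_bad_arg("`levels` must be non-empty")
  v_true <- v0 / (1 + (levels / IC50)^hill)
  sd <- noise_sd(noise, v_true)
  v <- pmax(0, with_seed(seed, v_true + stats::rnorm(length(v_true), 0, sd)))
  dr <- dose_response(levels, v, assay = assay)
  attr(dr, "provenance") <- list(source = "generate_dose_response",
                                 IC50 = IC50, hill = hill, v0 = v0,
                                 noise = unclass(noise), seed = seed)
  dr
}
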