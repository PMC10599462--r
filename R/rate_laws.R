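# Closed-form initial-rate laws for single-substrate and Bi-Bi mechanisms,
# in the Cleland convention: A is the leading substrate of ordered models,
# Ka/Kb are Michaelis constants, Kia is the dissociation constant of the E.A
# binary complex. Units are fixed package-wide: concentrations in mM, rates in
# the units of V (mM s^-1, or s^-1 when normalized by enzyme concentration).

#' Kinetic parameter set
#'
#' Container for the parameters of one mechanism model. Only the parameters a
#' given rate law requires need be present; constructors and rate laws validate
#' presence and positivity. If `kcat` is supplied, `E0` must be too and
#' `V = kcat * E0` is enforced (to 1e-9 relative); `V` is filled in when
#' missing.
#'
#' @param V Maximal rate (rate units). May be omitted when `kcat` and `E0`
#'   are given.
#' @param kcat Turnover number (s^-1), optional.
#' @param E0 Total enzyme concentration (mM), required with `kcat`.
#' @param Ka,Kb Michaelis constants of substrates A and B (mM).
#' @param Kia Dissociation constant of the E.A binary complex (mM).
#' @param Ksi Substrate-inhibition constant (mM).
#' @param alpha Interaction factor of the rapid-equilibrium random model
#'   (dimensionless).
#' @param KM Single-substrate Michaelis constant (mM).
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(V = 1, KM = 0.1)
#' kinetic_params(kcat = 17.7, E0 = 1e-6, KM = 0.081)
#' @export
kinetic_params <- function(V = NULL, kcat = NULL, E0 = NULL, Ka = NULL,
                           Kb = NULL, Kia = NULL, Ksi = NULL, alpha = NULL,
                           KM = NULL) {
  if (!is.null(kcat)) {
    if (is.null(E0)) stop_bad_arg("`kcat` requires `E0` (enzyme concentration)")
    if (is.null(V)) {
      V <- kcat * E0
    } else if (abs(V - kcat * E0) > 1e-9 * abs(V)) {
      stop_bad_arg("inconsistent parameters: V must equal kcat * E0")
    }
  }
  if (is.null(V)) stop_bad_arg("supply `V`, or `kcat` together with `E0`")
  p <- list(V = V, kcat = kcat, E0 = E0, Ka = Ka, Kb = Kb, Kia = Kia,
            Ksi = Ksi, alpha = alpha, KM = KM)
  for (nm in names(p)) {
    val <- p[[nm]]
    if (!is.null(val)) {
      if (!is.numeric(val) || length(val) != 1 || !is.finite(val) || val <= 0)
        stop_bad_arg("parameter `", nm, "` must be a single positive number")
    }
  }
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  set_ <- x[!vapply(x, is.null, logical(1))]
  cat("<kinetic_params> ",
      paste(names(set_), signif(unlist(set_), 6), sep = " = ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

MODEL_NAMES <- c("MM", "MM_SUBSTRATE_INHIBITION", "PING_PONG",
                 "ORDERED_STEADY_STATE", "RAPID_EQ_ORDERED",
                 "RAPID_EQ_RANDOM")

MODEL_REQUIRED <- list(
  MM = c("V", "KM"),
  MM_SUBSTRATE_INHIBITION = c("V", "KM", "Ksi"),
  PING_PONG = c("V", "Ka", "Kb"),
  ORDERED_STEADY_STATE = c("V", "Ka", "Kb", "Kia"),
  RAPID_EQ_ORDERED = c("V", "Kb", "Kia"),
  RAPID_EQ_RANDOM = c("V", "Ka", "Kb", "alpha")
)

#' Mechanism model descriptor
#'
#' Names one of the candidate kinetic mechanisms and, for ordered models, which
#' substrate label leads (binds first). The descriptor declares exactly which
#' parameters its rate law requires; see [required_params()].
#'
#' @param name One of `"MM"`, `"MM_SUBSTRATE_INHIBITION"`, `"PING_PONG"`,
#'   `"ORDERED_STEADY_STATE"`, `"RAPID_EQ_ORDERED"`, `"RAPID_EQ_RANDOM"`.
#' @param leading_substrate Label of the leading substrate for ordered models
#'   (e.g. `"NAD+"`); purely a label, the internal convention is that A leads.
#' @return An object of class `mechanism_model`.
#' @examples
#' mechanism_model("RAPID_EQ_ORDERED", leading_substrate = "NAD+")
#' @export
mechanism_model <- function(name, leading_substrate = "A") {
  name <- match.arg(name, MODEL_NAMES)
  structure(list(name = name, leading_substrate = leading_substrate),
            class = "mechanism_model")
}

#' @export
print.mechanism_model <- function(x, ...) {
  cat("<mechanism_model> ", x$name,
      if (x$name %in% c("ORDERED_STEADY_STATE", "RAPID_EQ_ORDERED"))
        paste0(" (leading substrate: ", x$leading_substrate, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Parameters required by a mechanism model
#'
#' @param model A [mechanism_model()] or model name.
#' @return Character vector of required parameter names.
#' @export
required_params <- function(model) {
  name <- if (inherits(model, "mechanism_model")) model$name else
    match.arg(model, MODEL_NAMES)
  MODEL_REQUIRED[[name]]
}

check_params <- function(p, required) {
  if (!inherits(p, "kinetic_params")) stop_bad_arg("`p` must be kinetic_params")
  missing <- required[vapply(p[required], is.null, logical(1))]
  if (length(missing))
    stop_bad_arg("missing required parameter(s): ",
                 paste(missing, collapse = ", "))
}

check_conc <- function(x, nm) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop_bad_arg("`", nm, "` must be finite and non-negative")
}

#' Michaelis-Menten rate law
#'
#' `v = V * S / (KM + S)`. Vectorized over `S`.
#'
#' @param S Substrate concentration (mM).
#' @param p [kinetic_params()] with `V` (or `kcat` + `E0`) and `KM`.
#' @return Rate in the units of `V`.
#' @examples
#' rate_mm(0.081, kinetic_params(kcat = 17.7, E0 = 1e-6, KM = 0.081))
#' @export
rate_mm <- function(S, p) {
  check_params(p, c("V", "KM"))
  check_conc(S, "S")
  p$V * S / (p$KM + S)
}

#' Michaelis-Menten rate law with uncompetitive substrate inhibition
#'
#' `v = V * S / (KM + S + S^2/Ksi)`, the standard single-site uncompetitive
#' form. The rate peaks at `S = sqrt(KM * Ksi)` and lies strictly below the
#' uninhibited law for all `S > 0`.
#'
#' @inheritParams rate_mm
#' @param p [kinetic_params()] with `V`, `KM` and `Ksi`.
#' @return Rate in the units of `V`.
#' @export
rate_mm_substrate_inhibition <- function(S, p) {
  check_params(p, c("V", "KM", "Ksi"))
  check_conc(S, "S")
  p$V * S / (p$KM + S + S^2 / p$Ksi)
}

#' Ping-pong (substituted enzyme) Bi-Bi rate law
#'
#' `v = V*A*B / (Kb*A + Ka*B + A*B)`. Double-reciprocal plots of this law are
#' parallel lines with slope `Ka/V` (varied A) at every fixed B.
#'
#' @param A,B Substrate concentrations (mM); vectorized with recycling.
#' @param p [kinetic_params()] with `V`, `Ka`, `Kb`.
#' @return Rate in the units of `V`.
#' @export
rate_ping_pong <- function(A, B, p) {
  check_params(p, c("V", "Ka", "Kb"))
  check_conc(A, "A"); check_conc(B, "B")
  p$V * A * B / (p$Kb * A + p$Ka * B + A * B)
}

#' Ordered steady-state Bi-Bi rate law
#'
#' `v = V*A*B / (Kia*Kb + Ka*B + Kb*A + A*B)` with A the leading substrate.
#'
#' @inheritParams rate_ping_pong
#' @param p [kinetic_params()] with `V`, `Ka`, `Kb`, `Kia`.
#' @return Rate in the units of `V`.
#' @export
rate_ordered_ss <- function(A, B, p) {
  check_params(p, c("V", "Ka", "Kb", "Kia"))
  check_conc(A, "A"); check_conc(B, "B")
  p$V * A * B / (p$Kia * p$Kb + p$Ka * B + p$Kb * A + A * B)
}

#' Rapid equilibrium ordered Bi-Bi rate law
#'
#' `v = V*A*B / (Kia*Kb + Kb*A + A*B)` with A binding first. The missing
#' `Ka*B` term (no E.B complex forms) is what places the varied-B
#' double-reciprocal intersection on the y axis and sends the varied-A
#' secondary slope replot through the origin.
#'
#' @inheritParams rate_ping_pong
#' @param p [kinetic_params()] with `V`, `Kb`, `Kia`.
#' @return Rate in the units of `V`.
#' @examples
#' p <- kinetic_params(V = 17.8, Kia = 0.05, Kb = 0.13)
#' rate_req_ordered(0.25, 0.125, p)
#' @export
rate_req_ordered <- function(A, B, p) {
  check_params(p, c("V", "Kb", "Kia"))
  check_conc(A, "A"); check_conc(B, "B")
  p$V * A * B / (p$Kia * p$Kb + p$Kb * A + A * B)
}

#' Rapid equilibrium random Bi-Bi rate law
#'
#' `v = V*A*B / (alpha*Ka*Kb + alpha*Kb*A + alpha*Ka*B + A*B)` where `alpha`
#' is the interaction factor coupling the two binding sites.
#'
#' @inheritParams rate_ping_pong
#' @param p [kinetic_params()] with `V`, `Ka`, `Kb`, `alpha`.
#' @return Rate in the units of `V`.
#' @export
rate_req_random <- function(A, B, p) {
  check_params(p, c("V", "Ka", "Kb", "alpha"))
  check_conc(A, "A"); check_conc(B, "B")
  a <- p$alpha
  p$V * A * B / (a * p$Ka * p$Kb + a * p$Kb * A + a * p$Ka * B + A * B)
}

#' Evaluate any mechanism's rate law
#'
#' Dispatcher used by the simulator and the global fitter. Single-substrate
#' models (`MM`, `MM_SUBSTRATE_INHIBITION`) read the varied substrate from `A`
#' and ignore `B`.
#'
#' @param model [mechanism_model()].
#' @param A,B Substrate concentrations (mM).
#' @param p [kinetic_params()].
#' @return Rate in the units of `V`.
#' @export
rate_law <- function(model, A, B = NULL, p) {
  stopifnot(inherits(model, "mechanism_model"))
  switch(model$name,
    MM = rate_mm(A, p),
    MM_SUBSTRATE_INHIBITION = rate_mm_substrate_inhibition(A, p),
    PING_PONG = rate_ping_pong(A, B, p),
    ORDERED_STEADY_STATE = rate_ordered_ss(A, B, p),
    RAPID_EQ_ORDERED = rate_req_ordered(A, B, p),
    RAPID_EQ_RANDOM = rate_req_random(A, B, p)
  )
}

#' Exact double-reciprocal slope and intercept
#'
#' For a Bi-Bi (or single-substrate) model, `1/v` is linear in the reciprocal
#' of the varied substrate at a fixed co-substrate concentration. This returns
#' the exact slope and intercept of that line, the analytical oracle behind
#' the primary-plot diagnostics. `MM_SUBSTRATE_INHIBITION` has no linear
#' reciprocal form and is rejected.
#'
#' @param model [mechanism_model()].
#' @param p [kinetic_params()] with the model's required parameters.
#' @param varied `"A"` or `"B"`, which substrate the line's abscissa varies.
#' @param fixed_conc Fixed co-substrate concentration (mM); vectorized.
#'   Ignored for `MM`.
#' @return A list with vectors `slope` and `intercept` (one entry per
#'   `fixed_conc`).
#' @examples
#' p <- kinetic_params(V = 17.8, Kia = 0.05, Kb = 0.13)
#' m <- mechanism_model("RAPID_EQ_ORDERED")
#' reciprocal_coefficients(m, p, varied = "B", fixed_conc = 0.1)$intercept
#' # = 1/V at every fixed A: the on-axis diagnostic
#' @export
reciprocal_coefficients <- function(model, p, varied = c("A", "B"),
                                    fixed_conc = NA_real_) {
  stopifnot(inherits(model, "mechanism_model"))
  varied <- match.arg(varied)
  check_params(p, required_params(model))
  V <- p$V
  if (model$name == "MM") {
    n <- max(1L, length(fixed_conc))
    return(list(slope = rep(p$KM / V, n), intercept = rep(1 / V, n)))
  }
  if (model$name == "MM_SUBSTRATE_INHIBITION")
    stop_bad_arg("MM_SUBSTRATE_INHIBITION has no linear double-reciprocal form")
  if (any(!is.finite(fixed_conc)) || any(fixed_conc <= 0))
    stop_bad_arg("`fixed_conc` must be positive")
  f <- fixed_conc
  out <- switch(model$name,
    PING_PONG = if (varied == "A") {
      list(slope = rep(p$Ka / V, length(f)),
           intercept = (1 / V) * (1 + p$Kb / f))
    } else {
      list(slope = rep(p$Kb / V, length(f)),
           intercept = (1 / V) * (1 + p$Ka / f))
    },
    ORDERED_STEADY_STATE = if (varied == "A") {
      list(slope = (p$Ka + p$Kia * p$Kb / f) / V,
           intercept = (1 / V) * (1 + p$Kb / f))
    } else {
      list(slope = (p$Kb / V) * (1 + p$Kia / f),
           intercept = (1 / V) * (1 + p$Ka / f))
    },
    RAPID_EQ_ORDERED = if (varied == "A") {
      list(slope = p$Kia * p$Kb / (V * f),
           intercept = (1 / V) * (1 + p$Kb / f))
    } else {
      list(slope = (p$Kb / V) * (1 + p$Kia / f),
           intercept = rep(1 / V, length(f)))
    },
    RAPID_EQ_RANDOM = if (varied == "A") {
      list(slope = (p$alpha * p$Ka / V) * (1 + p$Kb / f),
           intercept = (1 / V) * (1 + p$alpha * p$Kb / f))
    } else {
      list(slope = (p$alpha * p$Kb / V) * (1 + p$Ka / f),
           intercept = (1 / V) * (1 + p$alpha * p$Ka / f))
    }
  )
  out
}
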