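#' Concentration-time profile of an agent
#'
#' Defines the agent kinetics C(t) driving an effect model.  Three modes
#' are supported:
#' \describe{
#'   \item{bolus}{Intermittent boluses with monoexponential decay: each
#'     dose event contributes `peak * exp(-k (t - time))` for
#'     `t >= time`, with `k = ln(2)/t_half`; doses superpose.}
#'   \item{infusion}{Constant-rate infusions with first-order
#'     elimination: during an infusion the concentration approaches the
#'     plateau `css_target` as `css_target (1 - exp(-k (t - t0)))`; after
#'     the infusion ends the attained level decays with rate `k`.  The
#'     profile is parameterised by `(css_target, duration, t_half)`
#'     because flow-cell experiments control the plateau directly rather
#'     than a clearance/volume pair.}
#'   \item{interpolated}{Piecewise-linear interpolation of measured
#'     `(time, concentration)` points; 0 before the first point and
#'     hold-last-value after the final point (both flagged with a
#'     warning: conservative pre-dose, no spurious kill after records
#'     end).}
#' }
#'
#' @param agent_name Label for the agent (e.g. `"MEM"`).
#' @param mode One of `"bolus"`, `"infusion"`, `"interpolated"`.
#' @param events Data frame of dose events: columns `time` (h) and
#'   `peak` (bolus) or `time`, `css_target`, `duration` (infusion).
#' @param t_half Elimination half-life (h); required for bolus/infusion.
#' @param points Data frame with columns `time` and `conc`
#'   (interpolated mode); at least two rows, sorted, nonnegative.
#' @param unit Concentration unit label carried as metadata (e.g.
#'   `"mg/L"` or `"cu"`, where 1 cu = 1000 ng/mL = 1 mg/L).
#' @return An object of class `pk_profile`.
#' @examples
#' mem <- pk_profile("MEM", "bolus", events = data.frame(time = 24, peak = 107.53),
#'                   t_half = 0.893)
#' concentration(mem, c(24, 24.893))
#' @export
pk_profile <- function(agent_name, mode = c("bolus", "infusion", "interpolated"),
                       events = NULL, t_half = NULL, points = NULL, unit = "mg/L") {
  mode <- match.arg(mode)
  if (mode %in% c("bolus", "infusion")) {
    if (is.null(t_half) || !is.finite(t_half) || t_half <= 0)
      stop("t_half must be > 0 for bolus/infusion profiles")
    if (is.null(events)) # a never-dosed agent: C(t) identically 0
      events <- data.frame(time = numeric(0), peak = numeric(0),
                           css_target = numeric(0), duration = numeric(0))
    if (!is.data.frame(events)) stop("events must be a data frame")
    if (any(events$time < 0)) stop("dose times must be nonnegative")
    if (mode == "bolus") {
      if (!"peak" %in% names(events)) stop("bolus events need a 'peak' column")
      if (any(events$peak <= 0)) stop("peaks must be positive")
    } else {
      if (!all(c("css_target", "duration") %in% names(events)))
        stop("infusion events need 'css_target' and 'duration' columns")
      if (any(events$css_target <= 0)) stop("css_target must be positive")
      if (any(events$duration <= 0)) stop("duration must be positive")
    }
    events <- events[order(events$time), , drop = FALSE]
  } else {
    if (is.null(points) || !is.data.frame(points) ||
        !all(c("time", "conc") %in% names(points)) || nrow(points) < 2L)
      stop("interpolated mode needs a points data frame (time, conc) with >= 2 rows")
    if (is.unsorted(points$time, strictly = TRUE)) stop("point times must be strictly increasing")
    if (any(points$conc < 0) || any(points$time < 0)) stop("points must be nonnegative")
  }
  structure(list(agent_name = agent_name, mode = mode, events = events,
                 t_half = t_half, points = points, unit = unit),
            class = "pk_profile")
}

#' Named PK presets for the worked antibiotic examples
#'
#' Human-PK-matched flow-cell profiles: meropenem (MEM) peak 107.53 mg/L
#' with half-life 0.893 h; tobramycin (TOB, 10 mg/kg in a 70 kg adult)
#' peak 32.79 mg/L with half-life 2.75 h.
#'
#' @param agent `"MEM"` or `"TOB"`.
#' @param dose_times Bolus dose times (h); `NULL` gives a never-dosed
#'   profile (C identically 0), useful as the second agent of a
#'   two-agent model when only one drug is administered.
#' @param mode `"bolus"` (default) or `"infusion"` (MEM only; the peak
#'   becomes the infusion plateau).
#' @param duration Infusion duration (h) when `mode = "infusion"`.
#' @return A [pk_profile()].
#' @export
pk_preset <- function(agent = c("MEM", "TOB"), dose_times = 24,
                      mode = c("bolus", "infusion"), duration = 3) {
  agent <- match.arg(agent); mode <- match.arg(mode)
  peak   <- switch(agent, MEM = 107.53, TOB = 32.79)
  t_half <- switch(agent, MEM = 0.893,  TOB = 2.75)
  if (is.null(dose_times))
    return(pk_profile(agent, "bolus", events = NULL, t_half = t_half))
  if (mode == "bolus") {
    pk_profile(agent, "bolus", events = data.frame(time = dose_times, peak = peak),
               t_half = t_half)
  } else {
    pk_profile(agent, "infusion",
               events = data.frame(time = dose_times, css_target = peak, duration = duration),
               t_half = t_half)
  }
}

# ---- internal: exponential-atom representation -------------------------
# Bolus/infusion profiles decompose into atoms a*exp(-k*(t-start)) active on
# [start, end); k = 0 encodes a constant.  Atoms add, integrate and multiply
# in closed form, which the fast fitting path exploits.
.pk_atoms <- function(profile) {
  ev <- profile$events
  k <- log(2) / profile$t_half
  if (nrow(ev) == 0L)
    return(data.frame(a = numeric(0), k = numeric(0), start = numeric(0), end = numeric(0)))
  if (profile$mode == "bolus") {
    data.frame(a = ev$peak, k = k, start = ev$time, end = Inf)
  } else {
    do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
      t0 <- ev$time[i]; t1 <- t0 + ev$duration[i]; css <- ev$css_target[i]
      cend <- css * (1 - exp(-k * ev$duration[i]))
      data.frame(a = c(css, -css, cend), k = c(0, k, k),
                 start = c(t0, t0, t1), end = c(t1, t1, Inf))
    }))
  }
}

.atoms_eval <- function(atoms, t, left = FALSE) {
  out <- numeric(length(t))
  for (i in seq_len(nrow(atoms))) {
    on <- if (left) t > atoms$start[i] & t <= atoms$end[i]
          else      t >= atoms$start[i] & t < atoms$end[i]
    out[on] <- out[on] + atoms$a[i] * exp(-atoms$k[i] * (t[on] - atoms$start[i]))
  }
  out
}

# cumulative integral int_0^t of the atom sum, exact
.atoms_integral <- function(atoms, t) {
  out <- numeric(length(t))
  for (i in seq_len(nrow(atoms))) {
    tau <- pmin(t, atoms$end[i]) - atoms$start[i]
    tau <- pmax(tau, 0)
    out <- out + if (atoms$k[i] == 0) atoms$a[i] * tau
                 else atoms$a[i] / atoms$k[i] * (1 - exp(-atoms$k[i] * tau))
  }
  out
}

# product of two atom sets is again an atom set (on overlap windows)
.atoms_product <- function(a1, a2) {
  rows <- list()
  for (i in seq_len(nrow(a1))) for (j in seq_len(nrow(a2))) {
    s <- max(a1$start[i], a2$start[j]); e <- min(a1$end[i], a2$end[j])
    if (s >= e) next
    amp <- a1$a[i] * exp(-a1$k[i] * (s - a1$start[i])) *
           a2$a[j] * exp(-a2$k[j] * (s - a2$start[j]))
    rows[[length(rows) + 1L]] <- data.frame(a = amp, k = a1$k[i] + a2$k[j],
                                            start = s, end = e)
  }
  if (!length(rows)) data.frame(a = numeric(), k = numeric(),
                                start = numeric(), end = numeric())
  else do.call(rbind, rows)
}

#' Agent concentration at given times
#'
#' @param profile A [pk_profile()].
#' @param t Query times (h), nonnegative; vectorised.  Times before the
#'   first dose return 0.
#' @return Concentration(s) in the profile's unit.
#' @export
concentration <- function(profile, t) {
  stopifnot(inherits(profile, "pk_profile"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and nonnegative")
  if (profile$mode == "interpolated") {
    pts <- profile$points
    if (any(t < pts$time[1]))
      warning("query before first measured point: concentration taken as 0")
    if (any(t > pts$time[nrow(pts)]))
      warning("query after last measured point: last value held")
    out <- stats::approx(pts$time, pts$conc, xout = t, rule = 2)$y
    out[t < pts$time[1]] <- 0
    out
  } else {
    .atoms_eval(.pk_atoms(profile), t)
  }
}

# internal: left limit (value just before any dose at exactly t)
.concentration_left <- function(profile, t) {
  if (profile$mode == "interpolated") concentration(profile, t)
  else .atoms_eval(.pk_atoms(profile), t, left = TRUE)
}

# internal: exact cumulative integral of C for bolus/infusion; trapezoid on
# the knots (exact for a piecewise-linear interpolant) otherwise
.conc_integral <- function(profile, t) {
  if (profile$mode != "interpolated") return(.atoms_integral(.pk_atoms(profile), t))
  pts <- profile$points
  knots <- pts$time; vals <- pts$conc
  cum <- c(0, cumsum(diff(knots) * (vals[-1] + vals[-length(vals)]) / 2))
  vapply(t, function(ti) {
    if (ti <= knots[1]) return(0)
    if (ti >= knots[length(knots)]) {
      cum[length(cum)] + vals[length(vals)] * (ti - knots[length(knots)])
    } else {
      i <- findInterval(ti, knots)
      vi <- stats::approx(knots, vals, xout = ti)$y
      cum[i] + (ti - knots[i]) * (vals[i] + vi) / 2
    }
  }, numeric(1))
}

#' Solver breakpoints implied by a PK profile
#'
#' Times at which C(t) or its slope is discontinuous: dose times,
#' infusion ends and interpolation knots.  The dynamics integrator
#' restarts at these times so discontinuities are never smeared.
#'
#' @param profile A [pk_profile()].
#' @return Sorted vector of times (h).
#' @export
dose_breakpoints <- function(profile) {
  stopifnot(inherits(profile, "pk_profile"))
  bp <- switch(profile$mode,
    bolus        = profile$events$time,
    infusion     = c(profile$events$time, profile$events$time + profile$events$duration),
    interpolated = profile$points$time)
  sort(unique(bp))
}
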