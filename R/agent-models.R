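#' Single-agent effect-model parameters
#'
#' Parameters of a nonnegative effect function \eqn{h(C, B)} for one
#' agent.  The available models are
#' \describe{
#'   \item{linear}{\eqn{h = \theta_1 C B}: effect proportional to the
#'     product of agent concentration and biofilm.}
#'   \item{threshold}{\eqn{h = \theta_1 C B} if \eqn{C \ge \theta_2},
#'     else 0.  The boundary `C == theta2` counts as active.}
#'   \item{saturating}{\eqn{h = \theta_1 C/(\theta_2 + C)\, B}: Emax-type
#'     saturation; for large `C` the rate asymptotes to
#'     \eqn{\theta_1 B}.}
#' }
#' Whether the effect inhibits or stimulates growth is decided by the
#' sign convention in [model_spec()], not here: `h` is always >= 0.
#'
#' @param model One of `"linear"`, `"threshold"`, `"saturating"`.
#' @param theta1 Maximal/linear effect coefficient (1/h per
#'   concentration unit for linear/threshold; 1/h for saturating); >= 0.
#' @param theta2 Threshold concentration (threshold model) or
#'   half-effect concentration (saturating model); > 0 where used.
#' @param smooth If `TRUE` the threshold step is replaced by a logistic
#'   sigmoid of width `smooth_width` (useful for gradient-based
#'   optimisers); the exact step is the default.
#' @param smooth_width Width of the sigmoid (concentration units).
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(model = c("linear", "threshold", "saturating"),
                         theta1, theta2 = NULL,
                         smooth = FALSE, smooth_width = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(theta1), length(theta1) == 1L, is.finite(theta1))
  if (theta1 < 0) stop("theta1 must be nonnegative")
  if (model %in% c("threshold", "saturating")) {
    if (is.null(theta2) || !is.finite(theta2) || theta2 <= 0)
      stop(sprintf("model '%s' requires theta2 > 0", model))
  } else if (!is.null(theta2)) {
    stop("theta2 only applies to the threshold and saturating models")
  }
  if (smooth && model != "threshold")
    stop("smooth applies to the threshold model only")
  if (smooth && is.null(smooth_width)) smooth_width <- theta2 / 20
  structure(list(model = model, theta1 = theta1, theta2 = theta2,
                 smooth = smooth, smooth_width = smooth_width),
            class = "agent_params")
}

#' Two-agent effect-model parameters
#'
#' Parameters of a nonnegative joint effect function
#' \eqn{h(C_1, C_2, B)} for two agents:
#' \describe{
#'   \item{additive_linear}{\eqn{(\theta_1 C_1 + \theta_2 C_2) B}}
#'   \item{linear_interaction}{\eqn{(\theta_1 C_1 + \theta_2 C_2 +
#'     \theta_3 C_1 C_2) B}; \eqn{\theta_3} is the kill rate of the
#'     agents' interaction.}
#'   \item{competitive_interaction}{\eqn{scale \cdot
#'     \frac{C_1/C_{1,50} + \alpha C_2/C_{2,50}}
#'          {1 + C_1/C_{1,50} + C_2/C_{2,50}} B}; additivity for
#'     \eqn{\alpha > 0}, reducing to competitive antagonism at
#'     \eqn{\alpha = 0}.}
#'   \item{competitive_antagonism}{\eqn{scale \cdot
#'     \frac{C_1}{C_1 + C_{1,50}(1 + C_2/C_{2,50})} B}}
#' }
#' The competitive fractions are dimensionless, so a `scale` multiplier
#' (1/h, default 1) supplies the maximal kill rate left implicit in the
#' fraction form.
#'
#' @param model One of `"additive_linear"`, `"linear_interaction"`,
#'   `"competitive_interaction"`, `"competitive_antagonism"`.
#' @param theta1,theta2 Per-agent linear coefficients (1/h per
#'   concentration unit); >= 0.
#' @param theta3 Interaction coefficient (1/h per squared concentration
#'   unit); >= 0.
#' @param c1_50,c2_50 Half-effect concentrations; > 0 where used.
#' @param alpha Interaction parameter, >= 0 (competitive_interaction).
#' @param scale Overall rate multiplier (1/h) for the competitive
#'   models.
#' @return An object of class `two_agent_params`.
#' @export
two_agent_params <- function(model = c("additive_linear", "linear_interaction",
                                       "competitive_interaction", "competitive_antagonism"),
                             theta1 = NULL, theta2 = NULL, theta3 = NULL,
                             c1_50 = NULL, c2_50 = NULL, alpha = NULL, scale = 1) {
  model <- match.arg(model)
  pos    <- function(x, nm) if (is.null(x) || !is.finite(x) || x <= 0) stop(sprintf("%s must be > 0", nm))
  nonneg <- function(x, nm) if (is.null(x) || !is.finite(x) || x <  0) stop(sprintf("%s must be >= 0", nm))
  if (model %in% c("additive_linear", "linear_interaction")) {
    nonneg(theta1, "theta1"); nonneg(theta2, "theta2")
    if (model == "linear_interaction") nonneg(theta3, "theta3") else
      if (!is.null(theta3)) stop("theta3 only applies to linear_interaction")
  } else {
    pos(c1_50, "c1_50"); pos(c2_50, "c2_50"); nonneg(scale, "scale")
    if (model == "competitive_interaction") nonneg(alpha, "alpha") else
      if (!is.null(alpha)) stop("alpha only applies to competitive_interaction")
  }
  structure(list(model = model, theta1 = theta1, theta2 = theta2, theta3 = theta3,
                 c1_50 = c1_50, c2_50 = c2_50, alpha = alpha, scale = scale),
            class = "two_agent_params")
}

#' Single-agent effect rate h(C, B)
#'
#' @param params An [agent_params()] object.
#' @param C Agent concentration(s), >= 0.
#' @param B Biofilm level(s), >= 0.
#' @return Nonnegative effect rate(s), units/h; linear in `B`.
#' @examples
#' effect_single(agent_params("linear", theta1 = 1), C = 2, B = 3)
#' @export
effect_single <- function(params, C, B) {
  stopifnot(inherits(params, "agent_params"))
  if (any(!is.finite(C)) || any(C < 0)) stop("C must be finite and nonnegative")
  if (any(!is.finite(B)) || any(B < 0)) stop("B must be finite and nonnegative")
  with(params, switch(model,
    linear     = theta1 * C * B,
    threshold  = if (smooth) {
      theta1 * C * B / (1 + exp(-(C - theta2) / smooth_width))
    } else {
      ifelse(C >= theta2, theta1 * C * B, 0)
    },
    saturating = theta1 * C / (theta2 + C) * B))
}

#' Two-agent effect rate h(C1, C2, B)
#'
#' @param params A [two_agent_params()] object.
#' @param C1,C2 Agent concentrations, >= 0.
#' @param B Biofilm level(s), >= 0.
#' @return Nonnegative effect rate(s), units/h; linear in `B`.
#' @examples
#' p <- two_agent_params("competitive_interaction",
#'                       c1_50 = 1, c2_50 = 1, alpha = 1, scale = 1)
#' effect_two_agent(p, C1 = 1, C2 = 1, B = 1)  # 2/3
#' @export
effect_two_agent <- function(params, C1, C2, B) {
  stopifnot(inherits(params, "two_agent_params"))
  if (any(!is.finite(C1)) || any(C1 < 0) || any(!is.finite(C2)) || any(C2 < 0))
    stop("concentrations must be finite and nonnegative")
  if (any(!is.finite(B)) || any(B < 0)) stop("B must be finite and nonnegative")
  with(params, switch(model,
    additive_linear    = (theta1 * C1 + theta2 * C2) * B,
    linear_interaction = (theta1 * C1 + theta2 * C2 + theta3 * C1 * C2) * B,
    competitive_interaction =
      scale * (C1 / c1_50 + alpha * C2 / c2_50) /
              (1 + C1 / c1_50 + C2 / c2_50) * B,
    competitive_antagonism =
      scale * C1 / (C1 + c1_50 * (1 + C2 / c2_50)) * B))
}
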