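#' Ambiguity terms between control and treatment distributions
#'
#' Measures the overlap between the control and treatment parts of a model
#' as seen through one or more reference tumor fits: `t_star` is the
#' treatment posterior averaged over the treatment-attributed expectation,
#' and `c_star` the control posterior averaged over the control-attributed
#' expectation. Both lie in (0, 1]; 1 means the classes have disjoint
#' support, 0.5 means they are indistinguishable. Estimates from similar
#' past experiments feed the voxel-count power calculation [predict_z()].
#'
#' @param model A full `lpm_model`.
#' @param fits A `tumor_fit` or list of them (the reference fits whose
#'   weights set the class mixture).
#' @return A one-row tibble with `t_star` and `c_star`.
#' @export
ambiguity_terms <- function(model, fits) {
  if (inherits(fits, "tumor_fit")) fits <- list(fits)
  tr <- model$classes == "treatment"
  if (!any(tr)) abort("model has no treatment components")
  if (!any(!tr)) abort("model has no control components")
  num_t <- den_t <- num_c <- den_c <- 0
  for (fit in fits) {
    m_t <- as.vector(model$P[, tr, drop = FALSE] %*% fit$weights[tr])
    m_c <- as.vector(model$P[, !tr, drop = FALSE] %*% fit$weights[!tr])
    m <- m_t + m_c
    s <- m > 0
    num_t <- num_t + sum(m_t[s]^2 / m[s]); den_t <- den_t + sum(m_t[s])
    num_c <- num_c + sum(m_c[s]^2 / m[s]); den_c <- den_c + sum(m_c[s])
  }
  if (den_t == 0) abort("reference fits carry no treatment-attributed mass")
  if (den_c == 0) abort("reference fits carry no control-attributed mass")
  tibble::tibble(t_star = num_t / den_t, c_star = num_c / den_c)
}

#' Predicted Z-score as a function of voxel count
#'
#' The voxel-count power calculation: the Z-score attainable for a tumor
#' with `q_total` independent voxels given the ambiguity terms,
#' \deqn{Z = \sqrt{Q_{total}\,(T^* - (1 - T^* - C^*)^2 / (4 C^*))}.}
#' Z grows with the square root of the voxel count; ambiguity between
#' control and treated distributions (lower T*, C*) penalises it. A
#' negative bracket is clipped to zero and flagged via the `clipped`
#' attribute. The formula is an approximation, most accurate for strongly
#' responding tumors with well-separated (low-ambiguity) distributions.
#'
#' @param q_total Total voxel count QT + QC (vectorised).
#' @param t_star,c_star Ambiguity terms in (0, 1] (see
#'   [ambiguity_terms()]); `c_star` must be positive.
#' @param amb Alternatively, a tibble from [ambiguity_terms()].
#' @return Predicted Z (same length as `q_total`).
#' @export
predict_z <- function(q_total, t_star = NULL, c_star = NULL, amb = NULL) {
  if (!is.null(amb)) { t_star <- amb$t_star; c_star <- amb$c_star }
  if (any(q_total < 0)) abort("q_total must be non-negative")
  if (is.null(t_star) || is.null(c_star)) abort("ambiguity terms required")
  if (c_star <= 0) abort("c_star must be positive")
  bracket <- t_star - (1 - t_star - c_star)^2 / (4 * c_star)
  clipped <- bracket < 0
  z <- sqrt(q_total * max(bracket, 0))
  attr(z, "clipped") <- clipped
  z
}

#' Probability of observing at least one responder in a cohort
#'
#' Binomial detection probability: with a fraction `f` of tumors expected
#' to respond, the probability that a cohort of `n` contains at least one
#' detected responder is \eqn{\sum_{r=1}^{n} \binom{n}{r} f^r (1-f)^{n-r}}
#' (equivalently \eqn{1-(1-f)^n}).
#'
#' @param n Cohort size (positive integer, vectorised).
#' @param f Fraction of the cohort expected to respond, in \[0, 1\].
#' @return Detection probability.
#' @examples
#' detection_probability(5, 0.5)   # 0.96875
#' detection_probability(10, 0.2)  # 0.8926258
#' @export
detection_probability <- function(n, f) {
  if (any(n < 1) || any(n != floor(n))) abort("n must be a positive integer")
  if (any(f < 0 | f > 1)) abort("f must be in [0, 1]")
  mapply(function(ni, fi) sum(dbinom(seq_len(ni), size = ni, prob = fi)),
         n, f)
}

#' Smallest cohort reaching a target detection confidence
#'
#' @param f Fraction of the cohort expected to respond (0 < f \eqn{\le} 1).
#' @param target Required detection probability, in (0, 1).
#' @param n_max Search cap.
#' @return The smallest integer cohort size `n` with
#'   `detection_probability(n, f) >= target`.
#' @examples
#' min_cohort_for_confidence(0.5, 0.95)  # 5
#' @export
min_cohort_for_confidence <- function(f, target, n_max = 1000L) {
  if (f <= 0) abort("target confidence is unreachable when f = 0")
  if (f > 1) abort("f must be at most 1")
  if (target <= 0 || target >= 1) abort("target must be in (0, 1)")
  for (n in seq_len(n_max)) {
    if (detection_probability(n, f) >= target) return(n)
  }
  abort(sprintf("no cohort up to %d reaches the target", n_max))
}

#' Power curve tables
#'
#' Convenience emitters for the two power calculations: predicted Z versus
#' voxel count for a set of ambiguity terms, and detection probability
#' versus cohort size for a set of response fractions.
#'
#' @param q_grid Voxel counts to evaluate.
#' @param amb A tibble of ambiguity terms with columns `t_star`, `c_star`
#'   and optionally `label`.
#' @return A tidy tibble suitable for plotting or CSV export.
#' @export
power_z_table <- function(q_grid, amb) {
  if (!"label" %in% names(amb)) {
    amb$label <- sprintf("T*=%.2f, C*=%.2f", amb$t_star, amb$c_star)
  }
  purrr::pmap_dfr(amb, function(t_star, c_star, label) {
    tibble::tibble(label = label, q_total = q_grid,
                   z = as.numeric(predict_z(q_grid, t_star, c_star)))
  })
}

#' @rdname power_z_table
#' @param n_max Largest cohort size.
#' @param fractions Response fractions, each in (0, 1\].
#' @export
detection_table <- function(n_max = 12, fractions = c(0.2, 0.5, 0.8)) {
  tidyr::expand_grid(n = seq_len(n_max), f = fractions) |>
    dplyr::mutate(p_detection = detection_probability(.data$n, .data$f))
}

#' @rdname power_z_table
#' @param data A table from [power_z_table()] or [detection_table()].
#' @export
plot_power_z <- function(data) {
  ggplot(data, aes(x = .data$q_total, y = .data$z,
                   colour = .data$label)) +
    geom_line() +
    labs(x = "independent voxels (Q total)", y = "predicted Z score",
         colour = NULL, title = "Attainable power vs voxel count") +
    theme_minimal()
}

#' @rdname power_z_table
#' @export
plot_detection <- function(data) {
  ggplot(data, aes(x = .data$n, y = .data$p_detection,
                   colour = factor(.data$f))) +
    geom_line() + geom_point() +
    labs(x = "cohort size N", y = "P(at least one responder)",
         colour = "response fraction F") +
    theme_minimal()
}
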