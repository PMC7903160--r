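# Loss functions for the adversarial unlearning framework: the per-scanner
# main-task loss, the domain classification loss, the confusion loss that
# drives the domain classifier's softmax towards uniformity, multi-class soft
# Dice, and the Gaussian soft-label / KL machinery used to treat a continuous
# variable (age) as a distribution over 1-year bins.
#
# All logarithms are natural logs; probabilities are floored at
# `.prob_floor` inside logs so degenerate inputs give finite losses.

.prob_floor <- 1e-8

#' Loss weights for the combined adversarial objective
#'
#' Bundles the weights of the combined loss
#' \eqn{L = L_p + \alpha L_d + \beta L_{conf} + \sum_j (\gamma_j L_{c_j} +
#' \phi_j L_{Cconf_j})}: `alpha` scales the domain-classification term,
#' `beta` the confusion term, and each configured confound contributes a
#' classification weight `gamma` and a confusion weight `phi`.
#'
#' @param alpha non-negative weight of the domain classification loss.
#' @param beta non-negative weight of the confusion loss.
#' @param gamma named numeric vector of per-confound classification weights
#'   (may be empty).
#' @param phi named numeric vector of per-confound confusion weights; names
#'   must match `gamma`.
#' @return An object of class `loss_weights`.
#' @examples
#' loss_weights(alpha = 1, beta = 10)
#' @export
loss_weights <- function(alpha = 1, beta = 10,
                         gamma = numeric(), phi = numeric()) {
  if (length(gamma) != length(phi) ||
      !identical(sort(names(gamma)), sort(names(phi))))
    stop_unlearnr("unlearnr_error_weights",
                  "gamma and phi must name the same confounds")
  w <- c(alpha = alpha, beta = beta, gamma, phi)
  if (any(!is.finite(w)) || any(w < 0))
    stop_unlearnr("unlearnr_error_weights",
                  "all loss weights must be finite and >= 0")
  structure(list(alpha = alpha, beta = beta,
                 gamma = gamma, phi = phi[names(gamma)]),
            class = "loss_weights")
}

#' Main-task loss evaluated per scanner
#'
#' Evaluates a per-sample base loss separately for each scanner and returns
#' the sum over scanners of the within-scanner mean, so that every site
#' contributes equally to the optimisation regardless of its sample count.
#'
#' @param predictions predictions, one per sample (vector, or matrix with one
#'   row per sample).
#' @param labels true labels, matching `predictions` in shape.
#' @param domain_labels integer scanner label per sample.
#' @param base_loss function of (prediction, label) returning a per-sample
#'   loss vector; default squared error.
#' @return Scalar loss.
#' @examples
#' # two sites: errors (1, 9) -> mean 5, and (4) -> mean 4; total 9
#' per_scanner_task_loss(c(5, 7, 3), c(4, 4, 1), c(1, 1, 2))
#' @export
per_scanner_task_loss <- function(predictions, labels, domain_labels,
                                  base_loss = function(p, y) (p - y)^2) {
  n <- length(domain_labels)
  if (n == 0)
    stop_unlearnr("unlearnr_error_empty", "no samples supplied")
  if (is.matrix(predictions)) {
    per <- base_loss(predictions, labels)
  } else {
    per <- base_loss(as.numeric(predictions), as.numeric(labels))
  }
  if (length(per) != n)
    stop_unlearnr("unlearnr_error_shape",
                  "base_loss must return one value per sample")
  means <- tapply(per, factor(domain_labels), mean)
  sum(means)
}

#' Domain classification loss (categorical cross-entropy)
#'
#' Mean over the unlearning samples of the negative log softmax probability
#' assigned to the true scanner. Minimised when the domain classifier is
#' accurate; used to fit the classifier on a frozen representation and thereby
#' measure how much scanner information remains.
#'
#' @param domain_probs matrix (samples x N) of softmax outputs.
#' @param domain_labels integer true scanner per sample, in 1..N.
#' @return Scalar loss (nats).
#' @examples
#' domain_classification_loss(matrix(c(0.8, 0.2), 1), 1)  # -log 0.8
#' @export
domain_classification_loss <- function(domain_probs, domain_labels) {
  domain_probs <- .as_prob_matrix(domain_probs)
  n <- nrow(domain_probs)
  if (n < 1) stop_unlearnr("unlearnr_error_empty", "no unlearning samples")
  if (length(domain_labels) != n)
    stop_unlearnr("unlearnr_error_shape", "one label per row required")
  p_true <- domain_probs[cbind(seq_len(n), as.integer(domain_labels))]
  -mean(log(pmax(p_true, .prob_floor)))
}

#' Confusion loss
#'
#' Mean over samples of \eqn{-\frac{1}{N}\sum_k \log p_{s,k}}. Its global
#' minimum, \eqn{\log N}, is attained exactly when every softmax output is
#' uniform, i.e. when the domain classifier is maximally confused. Minimising
#' it with respect to the feature extractor removes scanner information from
#' the representation.
#'
#' @param domain_probs matrix (samples x N) of softmax outputs.
#' @return Scalar loss (nats), always `>= log(N)`.
#' @examples
#' confusion_loss(matrix(0.5, 2, 2))  # log 2
#' @export
confusion_loss <- function(domain_probs) {
  domain_probs <- .as_prob_matrix(domain_probs)
  if (nrow(domain_probs) < 1)
    stop_unlearnr("unlearnr_error_empty", "no unlearning samples")
  N <- ncol(domain_probs)
  -mean(rowSums(log(pmax(domain_probs, .prob_floor)))) / N
}

.as_prob_matrix <- function(p) {
  if (!is.matrix(p)) p <- matrix(p, nrow = 1)
  if (any(p < -1e-9) || any(abs(rowSums(p) - 1) > 1e-6))
    stop_unlearnr("unlearnr_error_probs",
                  "rows must be probability vectors summing to 1")
  p
}

#' Combined adversarial objective (bookkeeping aggregate)
#'
#' Combines the already-evaluated components into
#' \eqn{L_p + \alpha L_d + \beta L_{conf} + \sum_j(\gamma_j L_{c_j} + \phi_j
#' L_{Cconf_j})}. The optimiser never minimises this scalar directly — each
#' component is applied to its own parameter partition — but the aggregate is
#' logged per epoch.
#'
#' @param lp main-task loss.
#' @param ld domain classification loss.
#' @param lconf confusion loss.
#' @param weights a [loss_weights()] object.
#' @param confound_terms named list (one entry per confound) of
#'   `list(lc = ..., lcconf = ...)`.
#' @return Scalar.
#' @examples
#' total_unlearning_loss(1, 2, 3, loss_weights(alpha = 1, beta = 10))  # 33
#' @export
total_unlearning_loss <- function(lp, ld, lconf, weights,
                                  confound_terms = list()) {
  stopifnot(inherits(weights, "loss_weights"))
  vals <- c(lp, ld, lconf, unlist(confound_terms))
  if (length(vals) && any(!is.finite(vals)))
    stop_unlearnr("unlearnr_error_nonfinite", "component losses must be finite")
  total <- lp + weights$alpha * ld + weights$beta * lconf
  for (nm in names(confound_terms)) {
    ct <- confound_terms[[nm]]
    total <- total + weights$gamma[[nm]] * ct$lc + weights$phi[[nm]] * ct$lcconf
  }
  total
}

#' Multi-class soft Dice loss
#'
#' One minus the mean over the selected classes of the soft Dice coefficient
#' \eqn{(2|X \cap Y| + \epsilon) / (|X| + |Y| + \epsilon)}, with
#' probability-weighted overlap. A class absent from both prediction and
#' label contributes Dice 1 through \eqn{\epsilon}.
#'
#' @param class_probs matrix (voxels x classes) of per-voxel class
#'   probabilities, or an array whose last dimension indexes classes.
#' @param one_hot matching one-hot labels.
#' @param eps numerical stabiliser (default 1e-5).
#' @param classes integer indices of the classes averaged over (default all);
#'   for tissue segmentation set to the foreground classes so background is
#'   excluded.
#' @return Scalar in `[0, 1]` for hard predictions as `eps -> 0`.
#' @examples
#' p <- diag(2)[c(1, 1, 2, 2), ]; y <- diag(2)[c(1, 2, 2, 2), ]
#' multiclass_dice_loss(p, y, eps = 0)  # 1 - mean(2/3, 4/5)
#' @export
multiclass_dice_loss <- function(class_probs, one_hot, eps = 1e-5,
                                 classes = NULL) {
  class_probs <- .as_class_matrix(class_probs)
  one_hot <- .as_class_matrix(one_hot)
  if (!identical(dim(class_probs), dim(one_hot)))
    stop_unlearnr("unlearnr_error_shape",
                  "prediction and label shapes must match")
  if (is.null(classes)) classes <- seq_len(ncol(class_probs))
  num <- 2 * colSums(class_probs * one_hot) + eps
  den <- colSums(class_probs) + colSums(one_hot) + eps
  1 - mean((num / den)[classes])
}

.as_class_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  matrix(x, prod(d[-length(d)]), d[length(d)])
}

#' Gaussian soft label for a continuous variable
#'
#' Converts a scalar age into a probability distribution over 1-year bins by
#' evaluating the normal density \eqn{N(\mu = age, \sigma^2)} at the bin
#' centers and renormalising. The spread `sigma` (default 10 years) retains
#' the relative information between neighbouring bins, so that predicting 65
#' for a true 66 is rewarded over predicting 20.
#'
#' @param age true age in years, inside `bin_range`.
#' @param bin_range numeric length-2, inclusive range of bin centers
#'   (default `c(0, 100)`).
#' @param sigma Gaussian spread in years (default 10).
#' @return An object of class `soft_age_label` with fields `bin_centers`,
#'   `probs`, `mu`, `sigma`.
#' @examples
#' sl <- make_soft_label(50)
#' sum(sl$probs)  # 1
#' @export
make_soft_label <- function(age, bin_range = c(0, 100), sigma = 10) {
  if (age < bin_range[1] || age > bin_range[2])
    stop_unlearnr("unlearnr_error_range", "age outside the bin range")
  centers <- seq(bin_range[1], bin_range[2], by = 1)
  p <- stats::dnorm(centers, mean = age, sd = sigma)
  structure(list(bin_centers = centers, probs = p / sum(p),
                 mu = age, sigma = sigma),
            class = "soft_age_label")
}

#' KL-divergence task loss for soft-label regression
#'
#' \eqn{KL(\mathrm{true} \| \mathrm{predicted}) = \sum_k t_k \log(t_k/p_k)}
#' in nats; non-negative, zero iff the distributions coincide. The first
#' argument order is fixed: the true soft label is the reference.
#'
#' @param predicted_probs predicted distribution over the bins (vector, or
#'   matrix with one row per sample).
#' @param soft_label a [make_soft_label()] object, or a probability vector /
#'   matrix over the same bins.
#' @return Scalar (mean over samples when given matrices).
#' @examples
#' kl_task_loss(c(0.5, 0.5), c(0.75, 0.25))  # 0.1308
#' @export
kl_task_loss <- function(predicted_probs, soft_label) {
  t_ <- if (inherits(soft_label, "soft_age_label")) soft_label$probs else soft_label
  if (!is.matrix(predicted_probs)) {
    predicted_probs <- matrix(predicted_probs, nrow = 1)
    t_ <- matrix(t_, nrow = 1)
  }
  if (!is.matrix(t_)) t_ <- matrix(t_, nrow(predicted_probs), ncol(predicted_probs),
                                   byrow = TRUE)
  if (!identical(dim(t_), dim(predicted_probs)))
    stop_unlearnr("unlearnr_error_shape", "distributions must share bins")
  p <- pmax(predicted_probs, .prob_floor)
  terms <- ifelse(t_ > 0, t_ * (log(pmax(t_, .prob_floor)) - log(p)), 0)
  mean(rowSums(terms))
}

#' Point age estimate from a predicted bin distribution
#'
#' @param predicted_probs distribution over bins (vector or matrix, one row
#'   per sample).
#' @param bin_centers bin centers in years.
#' @param method `"expectation"` (default) or `"argmax"`.
#' @return Age(s) in years.
#' @examples
#' age_point_estimate(c(0.5, 0.5), c(40, 60))  # 50
#' @export
age_point_estimate <- function(predicted_probs, bin_centers,
                               method = c("expectation", "argmax")) {
  method <- match.arg(method)
  if (!is.matrix(predicted_probs))
    predicted_probs <- matrix(predicted_probs, nrow = 1)
  if (ncol(predicted_probs) != length(bin_centers))
    stop_unlearnr("unlearnr_error_shape", "one center per bin required")
  if (any(abs(rowSums(predicted_probs) - 1) > 1e-6))
    stop_unlearnr("unlearnr_error_probs", "rows must sum to 1")
  out <- switch(method,
    expectation = as.numeric(predicted_probs %*% bin_centers),
    argmax = bin_centers[max.col(predicted_probs, ties.method = "first")])
  if (length(out) == 1) out[[1]] else out
}
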