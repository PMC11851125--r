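# Training objective: CTC negative log-likelihood on the final head,
# intermediate CTC on tapped blocks, and a label-smoothed frame-level KL
# term, combined as gamma * L_ctc + beta * L_inter + (1 - gamma - beta) * L_kl.

.as_label_classes <- function(label) {
  if (length(label) == 1L && is.character(label)) {
    if (nchar(label) == 0L) return(integer(0))
    cl <- match(strsplit(label, "")[[1]], BASES)
    if (anyNA(cl)) stop("label must be over {A,C,G,T}")
    cl
  } else {
    as.integer(label)
  }
}

.check_post <- function(post) {
  if (!is.matrix(post) || (nrow(post) > 0L && ncol(post) != N_CLASSES))
    stop("posteriorgram must be a T x 5 matrix of log-probabilities")
  post
}

#' Loss weights for the combined objective
#'
#' @param gamma weight of the final-head CTC loss (default 0.3).
#' @param beta weight of the intermediate CTC loss (default 0.35). The KL
#'   term receives `1 - gamma - beta`.
#' @return A validated `loss_weights` list.
#' @export
loss_weights <- function(gamma = 0.3, beta = 0.35) {
  if (gamma < 0 || beta < 0 || gamma + beta > 1)
    stop("need gamma >= 0, beta >= 0, gamma + beta <= 1")
  structure(list(gamma = gamma, beta = beta), class = "loss_weights")
}

#' CTC negative log-likelihood
#'
#' The probability of a label under a posteriorgram is the sum over all
#' frame-level alignments (with blanks inserted and consecutive repeats
#' collapsed) that map to the label; this is computed by the forward dynamic
#' program in log space. Infeasible labels (longer than the frames can carry,
#' counting the blank required between repeated bases) yield `+Inf` together
#' with a classed warning `squeezecall_ctc_infeasible`.
#'
#' @param post T x 5 matrix of per-frame log-probabilities, blank last.
#' @param label DNA string over {A,C,G,T} (or an integer class vector).
#' @return Nonnegative real (possibly `+Inf`).
#' @export
ctc_loss <- function(post, label) {
  .check_post(post)
  cl <- .as_label_classes(label)
  res <- .ctc_forward_cpp(post, cl, FALSE, FALSE)
  if (!res$feasible)
    warning(warningCondition(
      sprintf("label of length %d infeasible for %d frames", length(cl),
              nrow(post)),
      class = "squeezecall_ctc_infeasible"))
  res$loss
}

# Loss plus gradient w.r.t. the head logits (softmax(logits) - gamma, where
# gamma are the CTC class posteriors). `post` must be the log-softmax of the
# logits. Internal: used by the trainer and by finite-difference tests.
.ctc_grad_logits <- function(post, label) {
  cl <- .as_label_classes(label)
  res <- .ctc_forward_cpp(post, cl, TRUE, FALSE)
  if (!res$feasible) return(list(loss = Inf, grad = NULL))
  list(loss = res$loss, grad = exp(post) - res$gamma)
}

#' Intermediate CTC loss over tapped blocks
#'
#' Mean of the CTC loss of each tapped block's own posteriorgram (every tap
#' carries its own projection head; weights are not shared with the final
#' head).
#'
#' @param taps named list of T x 5 log-probability matrices, one per tapped
#'   block (as produced by the encoder's intermediate heads).
#' @param label DNA string.
#' @param tap_set which taps to average over; defaults to all names in
#'   `taps`. Every requested tap must be present.
#' @return Nonnegative real.
#' @export
intermediate_ctc <- function(taps, label, tap_set = names(taps)) {
  if (length(tap_set) == 0L) stop("tap_set must be nonempty")
  tap_set <- as.character(tap_set)
  missing_taps <- setdiff(tap_set, names(taps))
  if (length(missing_taps))
    stop("missing tap(s): ", paste(missing_taps, collapse = ", "))
  mean(vapply(tap_set, function(b) ctc_loss(taps[[b]], label), 0))
}

#' Label smoothing
#'
#' Turns a hard class label into the smoothed target used by the KL loss:
#' the labelled class receives `1 - factor` and each of the other
#' `n_classes - 1` classes receives `factor / (n_classes - 1)`. With the
#' default 5-class alphabet and factor 0.1, class 2 gives
#' (0.025, 0.9, 0.025, 0.025, 0.025).
#'
#' @param class_index 1-based class index in `1..n_classes`.
#' @param n_classes number of classes (default 5: A, C, G, T, blank).
#' @param factor smoothing factor in `[0, 1)` (default 0.1).
#' @return Numeric probability vector of length `n_classes`.
#' @export
label_smooth <- function(class_index, n_classes = 5L, factor = 0.1) {
  if (factor < 0 || factor >= 1) stop("factor must be in [0, 1)")
  class_index <- as.integer(class_index)
  if (class_index < 1L || class_index > n_classes)
    stop("class_index must be in 1..n_classes")
  p <- rep(factor / (n_classes - 1L), n_classes)
  p[class_index] <- 1 - factor
  p
}

#' Frame-level label-smoothed KL loss
#'
#' Mean over labelled frames of `KL(label_smooth(y_t) || p_t)`, computed in
#' log space. The direction is fixed: the smoothed target is the reference
#' distribution. Frames with `NA` labels ("unknown") are skipped and the
#' normalizing count adjusted.
#'
#' @param post T x 5 matrix of log-probabilities.
#' @param frame_labels integer vector of length T with classes in 1..5 or NA.
#' @param factor smoothing factor (default 0.1).
#' @return Nonnegative real; 0 when no frame is labelled.
#' @export
kl_loss <- function(post, frame_labels, factor = 0.1) {
  .check_post(post)
  if (length(frame_labels) != nrow(post))
    stop("frame_labels length (", length(frame_labels),
         ") must equal the number of frames (", nrow(post), ")")
  keep <- which(!is.na(frame_labels))
  if (length(keep) == 0L) return(0)
  K <- ncol(post)
  Q <- t(vapply(frame_labels[keep],
                function(ci) label_smooth(ci, K, factor), numeric(K)))
  # KL(q||p) = sum q log q - sum q log p
  ent <- rowSums(Q * log(Q))
  cross <- rowSums(Q * post[keep, , drop = FALSE])
  mean(ent - cross)
}

# Loss plus gradient w.r.t. logits: (softmax(logits) - q_t) / T' on labelled
# frames, 0 elsewhere.
.kl_grad_logits <- function(post, frame_labels, factor = 0.1) {
  keep <- which(!is.na(frame_labels))
  grad <- matrix(0, nrow(post), ncol(post))
  if (length(keep) == 0L) return(list(loss = 0, grad = grad))
  K <- ncol(post)
  Q <- t(vapply(frame_labels[keep],
                function(ci) label_smooth(ci, K, factor), numeric(K)))
  grad[keep, ] <- (exp(post[keep, , drop = FALSE]) - Q) / length(keep)
  list(loss = kl_loss(post, frame_labels, factor), grad = grad)
}

#' Combined training loss
#'
#' `gamma * ctc_loss(final) + beta * intermediate_ctc + (1 - gamma - beta) *
#' kl_loss`, the weighted three-part objective used for training.
#'
#' @param final_post T x 5 log-probability matrix from the final head.
#' @param taps named list of intermediate-head posteriorgrams.
#' @param frame_labels per-frame classes (1..5 or NA) for the KL term.
#' @param label the chunk's base-sequence label (DNA string).
#' @param weights a [loss_weights()] object.
#' @return List with `total` and the three components `ctc`, `inter`, `kl`.
#' @export
combined_loss <- function(final_post, taps, frame_labels, label,
                          weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  l_ctc <- ctc_loss(final_post, label)
  l_int <- if (weights$beta > 0 || length(taps))
    intermediate_ctc(taps, label) else 0
  l_kl <- kl_loss(final_post, frame_labels)
  list(total = weights$gamma * l_ctc + weights$beta * l_int +
         (1 - weights$gamma - weights$beta) * l_kl,
       ctc = l_ctc, inter = l_int, kl = l_kl)
}

# Gradient of the combined loss w.r.t. final-head and tap-head logits.
# `ctc_norm = "label_length"` divides the CTC terms (loss and gradient) by the
# label length, the mean reduction used by mainstream CTC trainers; it puts
# the three loss terms on comparable per-symbol scales so the printed weights
# are meaningful. The default reproduces the plain weighted sum.
.combined_grad_logits <- function(final_post, taps, frame_labels, label,
                                  weights = loss_weights(),
                                  ctc_norm = c("none", "label_length")) {
  ctc_norm <- match.arg(ctc_norm)
  cl <- .as_label_classes(label)
  nrm <- if (ctc_norm == "label_length") max(1L, length(cl)) else 1L
  cg <- .ctc_grad_logits(final_post, label)
  if (!is.finite(cg$loss))
    return(list(total = Inf, feasible = FALSE))
  kg <- .kl_grad_logits(final_post, frame_labels)
  w_kl <- 1 - weights$gamma - weights$beta
  d_final <- (weights$gamma / nrm) * cg$grad + w_kl * kg$grad
  d_taps <- list()
  l_int <- 0
  if (length(taps)) {
    per <- weights$beta / (length(taps) * nrm)
    for (b in names(taps)) {
      tg <- .ctc_grad_logits(taps[[b]], label)
      if (!is.finite(tg$loss)) return(list(total = Inf, feasible = FALSE))
      l_int <- l_int + tg$loss / (length(taps) * nrm)
      d_taps[[b]] <- per * tg$grad
    }
  }
  list(total = weights$gamma * cg$loss / nrm + weights$beta * l_int +
         w_kl * kg$loss,
       ctc = cg$loss / nrm, inter = l_int, kl = kg$loss,
       d_final = d_final, d_taps = d_taps, feasible = TRUE)
}
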