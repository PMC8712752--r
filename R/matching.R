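# Propensity-score nearest-neighbour matching of EVT to non-EVT patients,
# with standardized-mean-difference balance diagnostics. Defaults follow
# common practice for greedy matching: no caliper, without replacement,
# treated processed in descending score order, equidistant controls broken
# by a seeded shuffle.

#' Fit a propensity model (logistic regression of treatment on covariates)
#'
#' @param records Data frame containing the covariates and a treatment
#'   indicator.
#' @param covariates Character vector of covariate column names (default:
#'   age, sex, NIHSS, ischemic core volume).
#' @param treated Logical vector (or name of a logical/0-1 column) marking
#'   treated patients.
#' @return A `propensity_model`: `coefficients`, per-patient `scores` in
#'   (0, 1), the fitted `glm`, and the covariate list.
#' @export
fit_propensity <- function(records,
                           covariates = c("age", "sex", "nihss", "core_volume"),
                           treated = "treated") {
  if (is.character(treated) && length(treated) == 1) {
    treated <- records[[treated]]
  }
  treated <- as.logical(treated)
  if (sum(treated) < 2 || sum(!treated) < 2) {
    stop("need at least 2 patients in each treatment group")
  }
  miss <- setdiff(covariates, names(records))
  if (length(miss)) stop("covariates not present: ", paste(miss, collapse = ", "))
  X <- records[, covariates, drop = FALSE]
  if (any(!vapply(X, function(col) all(is.finite(col) | is.character(col) | is.factor(col)),
                  TRUE))) {
    stop("covariates must be finite")
  }
  dat <- cbind(.treated = treated, X)
  fit <- suppressWarnings(
    glm(.treated ~ ., data = dat, family = binomial())
  )
  p <- fitted(fit)
  # perfect separation drives the deviance to zero (or prevents
  # convergence) with fitted probabilities pinned at 0/1; isolated extreme
  # fits from heavy-tailed covariates are tolerated
  extreme <- p < 1e-10 | p > 1 - 1e-10
  if (fit$deviance < 1e-6 || (!fit$converged && any(extreme))) {
    z <- abs(coef(fit))[-1]
    worst <- names(z)[which.max(z)]
    stop("propensity model shows separation; covariate '", worst,
         "' separates treated from controls")
  }
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  structure(list(coefficients = coef(fit), scores = as.numeric(p),
                 covariates = covariates, treated = treated, fit = fit),
            class = "propensity_model")
}

#' Greedy nearest-neighbour matching on the propensity score
#'
#' Treated patients are processed in descending score order; each is paired
#' with the unused (when `with_replacement = FALSE`) control minimising the
#' absolute score difference, subject to the caliper. Equidistant controls
#' are broken by taking the first in a seeded shuffle of the control list
#' (deterministic given `seed`).
#'
#' @param model A `propensity_model`, or a list with `scores` and `treated`.
#' @param caliper Maximum |score difference| allowed, or `NULL` for none.
#' @param with_replacement Allow a control to be reused.
#' @param seed Seed for the tie-breaking shuffle.
#' @param ids Optional patient identifiers (default: row index).
#' @return A `matched_set`: `pairs` data frame (`treated_id`, `control_id`,
#'   `score_treated`, `score_control`, `distance`), `unmatched_treated`,
#'   `unmatched_control`.
#' @export
nearest_neighbor_match <- function(model, caliper = NULL,
                                   with_replacement = FALSE, seed = 1L,
                                   ids = NULL) {
  scores <- model$scores
  treated <- model$treated
  if (is.null(ids)) ids <- seq_along(scores)
  t_idx <- which(treated); c_idx <- which(!treated)
  set.seed(seed)
  c_idx <- c_idx[sample.int(length(c_idx))]   # tie-break shuffle
  t_idx <- t_idx[order(scores[t_idx], decreasing = TRUE)]

  used <- logical(length(c_idx))
  pairs <- vector("list", length(t_idx))
  unmatched_t <- integer(0)
  for (k in seq_along(t_idx)) {
    i <- t_idx[k]
    avail <- if (with_replacement) seq_along(c_idx) else which(!used)
    if (!length(avail)) { unmatched_t <- c(unmatched_t, i); next }
    d <- abs(scores[c_idx[avail]] - scores[i])
    j <- avail[which.min(d)]                  # first minimum in shuffled order
    dist <- abs(scores[c_idx[j]] - scores[i])
    if (!is.null(caliper) && dist > caliper) {
      unmatched_t <- c(unmatched_t, i); next
    }
    used[j] <- TRUE
    pairs[[k]] <- data.frame(
      treated_id = ids[i], control_id = ids[c_idx[j]],
      score_treated = scores[i], score_control = scores[c_idx[j]],
      distance = dist, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, TRUE)])
  if (is.null(pairs)) {
    pairs <- data.frame(treated_id = character(0), control_id = character(0),
                        score_treated = numeric(0), score_control = numeric(0),
                        distance = numeric(0))
  }
  matched_controls <- unique(pairs$control_id)
  structure(list(
    pairs = pairs,
    unmatched_treated = ids[unmatched_t],
    unmatched_control = setdiff(ids[!treated], matched_controls),
    caliper = caliper,
    with_replacement = with_replacement
  ), class = "matched_set")
}

#' @export
print.matched_set <- function(x, ...) {
  cat(sprintf("<matched_set> %d pairs, %d unmatched treated, %d unmatched controls\n",
              nrow(x$pairs), length(x$unmatched_treated),
              length(x$unmatched_control)))
  invisible(x)
}

#' Standardized mean difference
#'
#' `(mean_treated - mean_control) / pooled SD`, the pooled SD taken from the
#' two groups with equal weight. A zero pooled SD yields SMD 0 with a
#' warning.
#'
#' @param x Covariate values.
#' @param treated Logical vector.
#' @return Scalar SMD.
#' @export
smd <- function(x, treated) {
  if (is.character(x)) x <- as.numeric(as.factor(x))
  m1 <- mean(x[treated]); m0 <- mean(x[!treated])
  s <- sqrt((var_or0(x[treated]) + var_or0(x[!treated])) / 2)
  if (s == 0) {
    if (m1 != m0) warning("zero pooled SD with unequal means; SMD reported as 0")
    return(0)
  }
  (m1 - m0) / s
}

var_or0 <- function(x) if (length(x) < 2) 0 else var(x)

#' Covariate balance before and after matching
#'
#' @param matched A `matched_set`.
#' @param records Data frame indexed by the ids used in matching.
#' @param model The `propensity_model` (for covariate names and treatment).
#' @param ids Patient identifiers aligned with `records` rows (default row
#'   index).
#' @return Data frame: covariate, SMD before matching (all treated vs all
#'   controls) and after (matched pairs only).
#' @export
balance_diagnostics <- function(matched, records, model, ids = NULL) {
  if (!nrow(matched$pairs)) stop("no matched pairs")
  if (is.null(ids)) ids <- seq_len(nrow(records))
  covs <- model$covariates
  treated <- model$treated
  t_rows <- match(matched$pairs$treated_id, ids)
  c_rows <- match(matched$pairs$control_id, ids)
  out <- lapply(covs, function(cv) {
    x <- records[[cv]]
    pre <- smd(x, treated)
    post_x <- c(x[t_rows], x[c_rows])
    post_t <- rep(c(TRUE, FALSE), each = nrow(matched$pairs))
    post <- smd(post_x, post_t)
    data.frame(covariate = cv, smd_before = pre, smd_after = post,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
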