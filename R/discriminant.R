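#' Assign modern samples to vegetation-system groups by HII thresholds
#'
#' Group 1 (native): `hii <= ip1`; group 3 (artificial): `hii >= ip2`;
#' group 2 (secondary): in between. When `ip2` is absent only groups 1 and
#' 2 are formed. Boundary conventions are inclusive at ip1 for group 1 and
#' at ip2 for group 3.
#'
#' @param meta a [site_meta()].
#' @param ips an `ip_estimate` from [estimate_ips()], or a numeric vector
#'   `c(ip1)` or `c(ip1, ip2)`.
#' @return data.frame of class `group_labels` with `sample_id` and `group`
#'   (integer 1/2/3); the thresholds used are kept in the `rule` attribute.
#' @export
assign_groups <- function(meta, ips) {
  rule <- ip_rule(ips)
  g <- ifelse(meta$hii <= rule[1], 1L,
              ifelse(!is.na(rule[2]) & meta$hii >= rule[2], 3L, 2L))
  structure(data.frame(sample_id = meta$sample_id, group = g,
                       stringsAsFactors = FALSE),
            class = c("group_labels", "data.frame"), rule = rule)
}

ip_rule <- function(ips) {
  if (inherits(ips, "ip_estimate")) {
    c(ip1 = ips$ip1, ip2 = ips$ip2)
  } else {
    ips <- as.numeric(ips)
    if (!length(ips) || is.na(ips[1])) stop("ip1 is required")
    c(ip1 = ips[1], ip2 = if (length(ips) >= 2) ips[2] else NA_real_)
  }
}

#' Linear discriminant model for vegetation-system groups
#'
#' Fits a Gaussian linear discriminant rule to modern pollen spectra with a
#' priori groups defined by the HII inflection points. Percentages are
#' square-root transformed; taxa present in fewer than `min_presence` of
#' the samples are dropped; and an orthogonal variance-reduction projection
#' (principal components retaining `var_keep` of the variance) is applied
#' before the discriminant fit to guard the rank of the pooled within-group
#' covariance. Priors are equal by default.
#'
#' @param pollen a percentage [pollen_matrix()] aligned to `labels`.
#' @param labels a `group_labels` from [assign_groups()].
#' @param min_presence minimum fraction of samples a taxon must occur in.
#' @param var_keep fraction of variance the projection retains.
#' @param priors `"equal"` or `"proportional"`.
#' @param sqrt_transform square-root transform the percentages first.
#' @return object of class `pollen_lda` wrapping the projection and the
#'   discriminant fit.
#' @export
pollen_lda <- function(pollen, labels, min_presence = 0.01, var_keep = 0.9,
                       priors = c("equal", "proportional"),
                       sqrt_transform = TRUE) {
  priors <- match.arg(priors)
  stopifnot(inherits(pollen, "pollen_matrix"))
  if (pollen$basis != "percentages")
    stop("pollen must be percentages; see to_percentages()")
  g <- labels$group[match(pollen$sample_ids, labels$sample_id)]
  if (anyNA(g)) stop("labels missing for some pollen samples")
  lev <- sort(unique(g))
  if (length(lev) < 2) stop("need at least 2 groups to fit a discriminant")
  keep <- colMeans(pollen$values > 0) >= min_presence
  if (sum(keep) < 2) stop("too few taxa pass the presence filter")
  X <- pollen$values[, keep, drop = FALSE]
  if (sqrt_transform) X <- sqrt(X)
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  d <- which(cum >= var_keep)[1]
  d <- min(d, nrow(X) - length(lev))      # keep covariance estimable
  if (any(tabulate(match(g, lev)) < d + 2))
    stop("a group has fewer than (retained dimension + 2) samples; ",
         "use a stronger variance reduction (smaller var_keep)")
  scores <- pca$x[, seq_len(d), drop = FALSE]
  prior <- if (priors == "equal") rep(1 / length(lev), length(lev)) else
    as.numeric(table(factor(g, lev)) / length(g))
  fit <- tryCatch(
    MASS::lda(scores, grouping = factor(g, levels = lev), prior = prior),
    error = function(e)
      stop("discriminant fit failed (", conditionMessage(e),
           "); try a stronger variance reduction"))
  structure(list(taxa = pollen$taxa[keep], sqrt_transform = sqrt_transform,
                 center = pca$center,
                 rotation = pca$rotation[, seq_len(d), drop = FALSE],
                 lda = fit, levels = lev, prior = prior,
                 groups = g, scores = scores),
            class = "pollen_lda")
}

# project new percentage assemblages into the model's discriminant space
lda_scores <- function(object, pollen) {
  Y <- pollen_values(pollen)
  miss <- setdiff(object$taxa, colnames(Y))
  if (length(miss))
    stop("pollen lacks model taxa (", paste(utils::head(miss, 5),
         collapse = ", "), "); run harmonize_taxa() first")
  X <- Y[, object$taxa, drop = FALSE]
  if (object$sqrt_transform) X <- sqrt(X)
  sweep(X, 2, object$center) %*% object$rotation
}

#' Posterior group probabilities for pollen assemblages
#'
#' @param object a [pollen_lda()] model.
#' @param newdata percentage pollen data over the model taxa.
#' @param ... unused.
#' @return list with `class` (predicted group) and `posterior` (matrix of
#'   per-group probabilities summing to 1 per sample).
#' @export
predict.pollen_lda <- function(object, newdata, ...) {
  pr <- stats::predict(object$lda, lda_scores(object, newdata))
  list(class = pr$class, posterior = pr$posterior)
}

#' @export
print.pollen_lda <- function(x, ...) {
  cat("Pollen discriminant model:", length(x$groups), "samples,",
      length(x$taxa), "taxa ->", ncol(x$rotation),
      "projected dimensions,", length(x$levels), "groups\n")
  cat("  group sizes:", paste(table(x$groups), collapse = " / "),
      "| priors:", paste(format(x$prior, digits = 3), collapse = " / "),
      "\n")
  invisible(x)
}

#' Leave-one-out confusion matrix of the discriminant rule
#'
#' Holds the variance-reduction projection fixed and refits the linear
#' discriminant without each sample in turn, classifying the held-out
#' sample. Reports counts (observed group x predicted group) and per-group
#' correct percentages.
#'
#' @inheritParams pollen_lda
#' @return object of class `confusion_matrix` with `counts` and
#'   `correct_pct`.
#' @export
loo_confusion <- function(pollen, labels, min_presence = 0.01,
                          var_keep = 0.9,
                          priors = c("equal", "proportional"),
                          sqrt_transform = TRUE) {
  model <- pollen_lda(pollen, labels, min_presence = min_presence,
                      var_keep = var_keep, priors = priors,
                      sqrt_transform = sqrt_transform)
  g <- factor(model$groups, levels = model$levels)
  sc <- model$scores
  n <- nrow(sc)
  pred <- integer(n)
  for (i in seq_len(n)) {
    fit <- MASS::lda(sc[-i, , drop = FALSE], grouping = g[-i],
                     prior = model$prior)
    pred[i] <- as.integer(as.character(
      stats::predict(fit, sc[i, , drop = FALSE])$class))
  }
  counts <- table(observed = g, predicted = factor(pred,
                                                   levels = model$levels))
  structure(list(counts = unclass(counts),
                 correct_pct = 100 * diag(unclass(counts)) /
                   rowSums(unclass(counts)),
                 n = n),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Leave-one-out confusion matrix (n =", x$n, ")\n")
  print(x$counts)
  cat("  per-group correct %:",
      paste(format(x$correct_pct, digits = 3), collapse = " / "), "\n")
  invisible(x)
}

#' Classify fossil pollen spectra as native or nonnative
#'
#' Applies the discriminant rule to fossil assemblages and merges the
#' secondary and artificial groups (2 and 3) into a single "nonnative"
#' posterior. A sample is called native when its native posterior exceeds
#' 0.5.
#'
#' @param model a [pollen_lda()] fit.
#' @param fossil a percentage `pollen_matrix` harmonized to the model taxa.
#' @return data.frame of class `fossil_classification` with per-group
#'   posteriors, `native_posterior`, `nonnative_posterior` and `call`.
#' @export
classify_fossil <- function(model, fossil) {
  ids <- if (inherits(fossil, "pollen_matrix")) fossil$sample_ids else
    rownames(pollen_values(fossil))
  pr <- predict(model, fossil)
  post <- pr$posterior
  native <- post[, as.character(1)]
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (lv in colnames(post)) out[[paste0("posterior_", lv)]] <- post[, lv]
  out$native_posterior <- native
  out$nonnative_posterior <- 1 - native
  out$call <- ifelse(native > 0.5, "native", "nonnative")
  structure(out, class = c("fossil_classification", "data.frame"))
}

#' Merge per-sample calls into contiguous vegetation phases
#'
#' Contiguous runs of identical native/nonnative calls become phases with
#' start and end ages. Runs shorter than `min_run` samples are absorbed
#' into a neighbouring phase (the longer neighbour wins; on a tie, the
#' older phase).
#'
#' @param fc a [classify_fossil()] result (or any vector of calls via
#'   `fc$call`).
#' @param ages ages (cal yr BP) aligned to the fossil samples, nondecreasing
#'   (youngest first).
#' @param min_run minimum run length kept as its own phase.
#' @return data.frame with `phase`, `call`, `age_young`, `age_old`,
#'   `n_samples`.
#' @export
call_phases <- function(fc, ages, min_run = 2) {
  calls <- if (is.data.frame(fc)) fc$call else as.character(fc)
  if (length(calls) != length(ages))
    stop("ages must align with the classified fossil samples")
  repeat {
    r <- rle(calls)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_run)
    if (!length(short)) break
    j <- short[1]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    left <- if (j > 1) r$lengths[j - 1] else -Inf
    right <- if (j < length(r$lengths)) r$lengths[j + 1] else -Inf
    # longer neighbour wins; tie -> older phase (larger ages = later index)
    into <- if (right >= left) j + 1 else j - 1
    calls[starts[j]:ends[j]] <- r$values[into]
  }
  r <- rle(calls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(phase = seq_along(r$lengths), call = r$values,
             age_young = ages[starts], age_old = ages[ends],
             n_samples = r$lengths, stringsAsFactors = FALSE)
}
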