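## Aligned-rank-transform (ART) factorial ANOVA.
##
## Nonparametric factorial testing: for each effect in the model, the
## response is "aligned" by removing the estimated contributions of every
## other effect (cell-mean algebra via the full fixed-effects model), the
## aligned values are ranked (mid-ranks for ties), and a full factorial
## ANOVA is fitted to the ranks -- from which only that effect's F test is
## kept. Replicate microcosms are treated as independent observations
## (fixed-effects model, no random replicate term).

.art_prepare <- function(formula, data) {
  vars <- all.vars(formula)
  response <- vars[1L]
  factors <- vars[-1L]
  if (length(factors) < 2L)
    stop("ART needs at least a two-factor model", call. = FALSE)
  data <- as.data.frame(data)
  if (!all(vars %in% names(data)))
    stop("data is missing variables: ",
         paste(setdiff(vars, names(data)), collapse = ", "), call. = FALSE)
  if (anyNA(data[vars]))
    stop("missing values in response or factors", call. = FALSE)
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2L)
      stop("factor '", f, "' has fewer than 2 levels", call. = FALSE)
  }
  cells <- table(data[factors])
  if (any(cells == 0L)) {
    idx <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    cell <- paste(factors, "=", mapply(function(f, i)
      dimnames(cells)[[f]][i], seq_along(factors), idx), collapse = ", ")
    stop("empty design cell (", cell, "): interaction inestimable",
         call. = FALSE)
  }
  contrasts <- lapply(setNames(factors, factors),
                      function(f) "contr.sum")
  full <- as.formula(paste(response, "~",
                           paste(factors, collapse = " * ")))
  list(data = data, response = response, factors = factors,
       full = full, contrasts = contrasts)
}

#' Align (and rank) a factorial response for one effect
#'
#' Strips from the response the estimated contributions of every effect in
#' the full factorial model except `target`, leaving that effect plus
#' residual noise, then assigns mid-ranks. Contributions are the
#' coefficient partition of the full fixed-effects fit under sum-to-zero
#' contrasts, so for balanced designs the aligned values have zero marginal
#' means for every stripped effect.
#'
#' @param formula Model formula, e.g. `flux ~ temperature * flooding`; the
#'   right-hand side is expanded to the full factorial.
#' @param data data.frame with the response and factor columns.
#' @param target Effect to retain: a term label such as `"temperature"` or
#'   `"temperature:flooding"`.
#' @return List: `aligned` (pre-rank aligned response), `ranks` (mid-ranks
#'   of `aligned`), `target`.
#' @export
art_align <- function(formula, data, target) {
  prep <- .art_prepare(formula, data)
  m <- lm(prep$full, data = prep$data, contrasts = prep$contrasts)
  labels <- attr(terms(m), "term.labels")
  target <- gsub(" ", "", target)
  canon <- function(lab) vapply(strsplit(lab, ":", fixed = TRUE),
                                function(p) paste(sort(p), collapse = ":"),
                                character(1L))
  k <- match(canon(target), canon(labels))
  if (is.na(k))
    stop("target '", target, "' is not a term of the model (terms: ",
         paste(labels, collapse = ", "), ")", call. = FALSE)
  X <- model.matrix(m)
  assign <- attr(X, "assign")
  beta <- coef(m)
  contribution <- as.numeric(X[, assign == k, drop = FALSE] %*%
                               beta[assign == k])
  aligned <- residuals(m) + contribution
  list(aligned = unname(aligned), ranks = rank(aligned),
       target = labels[k])
}

#' Factorial ANOVA of aligned rank transformed data
#'
#' Runs the full ART procedure: each effect of the factorial model (main
#' effects and all interactions) is aligned with [art_align()], ranked, and
#' tested with a fixed-effects ANOVA on the ranks; only the aligned effect's
#' F statistic is retained from each fit. Marginal (type III style) sums of
#' squares under sum-to-zero contrasts are used, so unbalanced designs are
#' handled; for balanced designs these coincide with the classical
#' decomposition.
#'
#' @inheritParams art_align
#' @return Object of class `art_anova`: data.frame with one row per effect
#'   (`term`, `df`, `df_res`, `F_value`, `p_value`).
#' @examples
#' d <- expand.grid(temperature = c("27", "30"), flooding = c("wet", "dry"),
#'                  replicate = 1:4)
#' d$flux <- rnorm(nrow(d)) + (d$flooding == "wet") * 2
#' art_anova(flux ~ temperature * flooding, d)
#' @export
art_anova <- function(formula, data) {
  prep <- .art_prepare(formula, data)
  m0 <- lm(prep$full, data = prep$data, contrasts = prep$contrasts)
  labels <- attr(terms(m0), "term.labels")
  rows <- lapply(labels, function(lab) {
    al <- art_align(formula, prep$data, lab)
    d <- prep$data
    d$.rank <- al$ranks
    rf <- as.formula(paste(".rank ~",
                           paste(prep$factors, collapse = " * ")))
    mr <- lm(rf, data = d, contrasts = prep$contrasts)
    a <- car::Anova(mr, type = 3)
    i <- match(lab, rownames(a))
    data.frame(term = lab,
               df = as.integer(a$Df[i]),
               df_res = as.integer(a$Df[rownames(a) == "Residuals"]),
               F_value = a$`F value`[i],
               p_value = a$`Pr(>F)`[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("art_anova", "data.frame")
  out
}

#' @export
print.art_anova <- function(x, ...) {
  cat("ANOVA of aligned rank transformed data\n")
  y <- data.frame(term = x$term, df = x$df,
                  F = sprintf("%.3f", x$F_value),
                  p = format.pval(x$p_value, digits = 3, eps = 1e-16))
  print(y, row.names = FALSE)
  invisible(x)
}
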