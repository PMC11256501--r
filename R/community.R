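## Amplicon count-table summaries: rarefaction, relative abundance, curated
## CH4-cycling guild extraction, and CLAM generalist/specialist niche
## classification.
##
## Count tables are integer matrices with samples as rows and taxa as
## columns (vegan convention); taxonomy lineage strings are carried
## separately as a character vector named by taxon id.

#' Rarefy a count table to a common depth
#'
#' Subsamples each sample's counts without replacement (multivariate
#' hypergeometric, via [vegan::rrarefy()]) to exactly `depth` reads. Samples
#' whose total is below `depth` cannot be rarefied and are dropped; their ids
#' are reported in the `"dropped_samples"` attribute.
#'
#' @param counts Integer matrix, samples x taxa.
#' @param depth Target depth (reads per sample), default 29300.
#' @param seed Optional integer seed for reproducible subsampling.
#' @return Rarefied count matrix (every row sums to `depth`), with attribute
#'   `dropped_samples` naming the removed samples.
#' @export
rarefy_counts <- function(counts, depth = 29300, seed = NULL) {
  counts <- as.matrix(counts)
  if (length(depth) != 1L || !is.finite(depth) || depth <= 0)
    stop("depth must be a single positive number", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  totals <- rowSums(counts)
  keep <- totals >= depth
  dropped <- rownames(counts)[!keep]
  if (!any(keep))
    stop("no sample reaches the rarefaction depth ", depth, call. = FALSE)
  kept <- counts[keep, , drop = FALSE]
  at_depth <- rowSums(kept) == depth
  out <- kept
  if (any(!at_depth)) {
    sub <- kept[!at_depth, , drop = FALSE]
    ## rrarefy warns whenever the smallest positive count exceeds 1; that
    ## heuristic is irrelevant for already-aggregated tables, so muffle it
    quiet_rrarefy <- function(x, n) withCallingHandlers(
      vegan::rrarefy(x, n),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    rar <- if (is.null(seed)) quiet_rrarefy(sub, depth) else
      withr::with_seed(seed, quiet_rrarefy(sub, depth))
    out[!at_depth, ] <- rar
  }
  storage.mode(out) <- "integer"
  attr(out, "dropped_samples") <- dropped
  out
}

#' Per-sample relative abundances
#'
#' @param counts Matrix, samples x taxa, with positive row totals.
#' @return Matrix of proportions; each row sums to 1.
#' @export
relative_abundance <- function(counts) {
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  if (any(totals <= 0))
    stop("samples with zero total counts: ",
         paste(rownames(counts)[totals <= 0], collapse = ", "),
         call. = FALSE)
  sweep(counts, 1L, totals, "/")
}

#' Curated CH4-cycling guild membership
#'
#' Taxon names (genus- or class-level) with reported methanogenic
#' (mcrABC-bearing) or methanotrophic (pmoCAB/mmoX-bearing) capability, used
#' to pull CH4-cycling guilds out of a general 16S count table.
#'
#' @return List with character vectors `methanogens` and `methanotrophs`.
#' @export
curated_guilds <- function() {
  list(
    methanogens = c("Methanobacterium", "Candidatus Methanomethylicus",
                    "Methanobacteria", "Methanocella",
                    "Methanomassiliicoccus", "Methanosaeta",
                    "Methanosarcina", "Bathyarchaeia", "Thermoplasmatales"),
    methanotrophs = c("Methylocystis", "Candidatus Methanoperedens",
                      "Candidatus Methylospira", "Methylomirabilaceae",
                      "Methylomonas", "Methylosinus", "Methylovirgula",
                      "RCP2-54")
  )
}

## Split "d__Archaea;p__...;g__Methanobacterium" into clean rank tokens.
.taxonomy_tokens <- function(lineage) {
  toks <- strsplit(lineage, ";", fixed = TRUE)
  lapply(toks, function(x) {
    x <- trimws(sub("^[a-zA-Z]__", "", trimws(x)))
    x[nzchar(x)]
  })
}

#' Extract methanogen and methanotroph guild subtables
#'
#' Matches every taxon's taxonomy string against the curated guild lists
#' (case-insensitive exact match on any rank token) and returns the guild
#' subtables together with per-sample summed relative abundances -- the
#' quantity usually reported as "relative abundance of total methanogens /
#' methanotrophs".
#'
#' @param counts Matrix, samples x taxa; column names are taxon ids.
#' @param taxonomy Character vector of semicolon-delimited lineage strings,
#'   one per taxon (named by taxon id or in column order).
#' @param guilds Guild configuration, see [curated_guilds()]. A name present
#'   in both lists is a configuration error.
#' @return List: `methanogens` and `methanotrophs` (count submatrices),
#'   `summary` (data.frame of per-sample summed relative abundance per
#'   guild), and `matches` (data.frame taxon / guild / matched name).
#' @export
extract_guilds <- function(counts, taxonomy, guilds = curated_guilds()) {
  counts <- as.matrix(counts)
  both <- intersect(tolower(guilds$methanogens),
                    tolower(guilds$methanotrophs))
  if (length(both))
    stop("guild names present in both lists: ",
         paste(both, collapse = ", "), call. = FALSE)
  if (is.null(names(taxonomy))) {
    if (length(taxonomy) != ncol(counts))
      stop("taxonomy must be named by taxon or match ncol(counts)",
           call. = FALSE)
    names(taxonomy) <- colnames(counts)
  }
  taxonomy <- taxonomy[colnames(counts)]
  if (anyNA(taxonomy))
    stop("taxonomy strings missing for some taxa", call. = FALSE)
  tokens <- .taxonomy_tokens(taxonomy)
  match_one <- function(toks, list_lc) {
    hit <- which(tolower(toks) %in% list_lc)
    if (length(hit)) toks[hit[1L]] else NA_character_
  }
  gen_lc <- tolower(guilds$methanogens)
  oth_lc <- tolower(guilds$methanotrophs)
  gen_hit <- vapply(tokens, match_one, character(1L), list_lc = gen_lc)
  oth_hit <- vapply(tokens, match_one, character(1L), list_lc = oth_lc)
  ambiguous <- !is.na(gen_hit) & !is.na(oth_hit)
  if (any(ambiguous))
    stop("taxa match both guilds: ",
         paste(colnames(counts)[ambiguous], collapse = ", "),
         call. = FALSE)
  is_gen <- !is.na(gen_hit)
  is_oth <- !is.na(oth_hit)
  rel <- relative_abundance(counts)
  summary <- data.frame(
    sample = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    methanogen_rel_abund = rowSums(rel[, is_gen, drop = FALSE]),
    methanotroph_rel_abund = rowSums(rel[, is_oth, drop = FALSE]),
    row.names = NULL)
  matches <- data.frame(
    taxon = colnames(counts)[is_gen | is_oth],
    guild = c(rep("methanogen", sum(is_gen)),
              rep("methanotroph", sum(is_oth)))[
      order(c(which(is_gen), which(is_oth)))],
    matched_name = c(gen_hit[is_gen], oth_hit[is_oth])[
      order(c(which(is_gen), which(is_oth)))],
    row.names = NULL)
  list(methanogens = counts[, is_gen, drop = FALSE],
       methanotrophs = counts[, is_oth, drop = FALSE],
       summary = summary,
       matches = matches)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' CLAM multinomial niche classification
#'
#' Classifies each taxon as a habitat generalist, a specialist of group A or
#' B, or too rare to classify, from its pooled counts in two disjoint sample
#' groups. A taxon with pooled counts (yA, yB), total n = yA + yB, is a
#' specialist of A when the one-sided exact binomial test rejects
#' `H0: pA <= pi` at level `alpha` (p-value `P(Y >= yA | n, pi)`) with the
#' supermajority threshold `pi = specialization` (default 2/3); symmetrically
#' for B. Neither test rejecting gives a generalist. `alpha` is the
#' individual-test level, applied directly to each one-sided test.
#'
#' Two readings of the coverage limit are available: `"count_floor"`
#' (default) marks taxa with total counts below `coverage_limit` as too
#' rare; `"min_classifiable"` marks taxa whose total is too small for either
#' test ever to reject (i.e. `specialization^n > alpha` even with every
#' count in one group).
#'
#' Equal sampling effort in the two groups is assumed (balanced designs
#' rarefied to a common depth).
#'
#' @param countsA,countsB Count matrices (samples x taxa, identical taxa) or
#'   per-taxon pooled count vectors for the two groups. Matrices sharing
#'   sample ids are rejected as overlapping groups.
#' @param alpha Level of each one-sided test, in (0, 1).
#' @param specialization Supermajority threshold pi, in (0.5, 1).
#' @param coverage_limit Minimum total count for classification under the
#'   `"count_floor"` rule.
#' @param coverage_rule `"count_floor"` or `"min_classifiable"`.
#' @return Object of class `clam_classification`: data.frame with `taxon`,
#'   `yA`, `yB`, `label` (factor: generalist, specialist_A, specialist_B,
#'   too_rare); attributes `params` and `label_counts`.
#' @export
clam_classify <- function(countsA, countsB, alpha = 0.05,
                          specialization = 2 / 3, coverage_limit = 10,
                          coverage_rule = c("count_floor",
                                            "min_classifiable")) {
  coverage_rule <- match.arg(coverage_rule)
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (specialization <= 0.5 || specialization >= 1)
    stop("specialization threshold must be in (0.5, 1)", call. = FALSE)
  pool <- function(x) {
    if (is.matrix(x) || is.data.frame(x)) colSums(as.matrix(x)) else x
  }
  if ((is.matrix(countsA) || is.data.frame(countsA)) &&
      (is.matrix(countsB) || is.data.frame(countsB))) {
    shared <- intersect(rownames(countsA), rownames(countsB))
    if (length(shared))
      stop("groups share samples: ", paste(shared, collapse = ", "),
           call. = FALSE)
  }
  yA <- pool(countsA)
  yB <- pool(countsB)
  if (length(yA) != length(yB))
    stop("groups must cover the same taxa", call. = FALSE)
  if (any(yA < 0) || any(yB < 0) ||
      any(yA != round(yA)) || any(yB != round(yB)))
    stop("counts must be non-negative integers", call. = FALSE)
  n <- yA + yB
  too_rare <- switch(coverage_rule,
    count_floor = n < coverage_limit,
    min_classifiable = specialization^n > alpha)
  ## one-sided exact binomial p-values P(Y >= y | n, pi)
  pA <- pbinom(yA - 1, n, specialization, lower.tail = FALSE)
  pB <- pbinom(yB - 1, n, specialization, lower.tail = FALSE)
  spec_A <- !too_rare & pA <= alpha
  spec_B <- !too_rare & pB <= alpha
  label <- factor(
    ifelse(too_rare, "too_rare",
           ifelse(spec_A, "specialist_A",
                  ifelse(spec_B, "specialist_B", "generalist"))),
    levels = c("generalist", "specialist_A", "specialist_B", "too_rare"))
  taxa <- names(yA) %||% paste0("taxon_", seq_along(yA))
  out <- data.frame(taxon = taxa, yA = unname(yA), yB = unname(yB),
                    label = label, row.names = NULL)
  class(out) <- c("clam_classification", "data.frame")
  attr(out, "params") <- list(alpha = alpha,
                              specialization = specialization,
                              coverage_limit = coverage_limit,
                              coverage_rule = coverage_rule)
  attr(out, "label_counts") <- table(label)
  out
}

#' @export
print.clam_classification <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "CLAM niche classification (%d taxa; alpha = %g, pi = %.3f, coverage %s = %g)\n",
    nrow(x), p$alpha, p$specialization, p$coverage_rule, p$coverage_limit))
  print(attr(x, "label_counts"))
  invisible(x)
}
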