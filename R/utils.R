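# shared internal helpers

# stop() with the offending field name; used by all spec validators
failField <- function(field, why) {
  stop(sprintf("invalid field '%s': %s", field, why), call. = FALSE)
}

checkCount <- function(x, field, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != floor(x))
    failField(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

checkFraction <- function(x, field) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    failField(field, "must lie in [0, 1]")
  as.numeric(x)
}

checkPositive <- function(x, field) {
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    failField(field, "must be a single positive number")
  as.numeric(x)
}

# DE tables are plain data.frames with a fixed schema so every stage composes
DE_COLUMNS <- c("gene", "log2FC", "SE", "p", "padj")

assertDETable <- function(de, need_se = FALSE, what = "DE table") {
  if (!is.data.frame(de))
    stop(what, " must be a data.frame", call. = FALSE)
  missing <- setdiff(setdiff(DE_COLUMNS, "SE"), colnames(de))
  if (length(missing))
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (need_se && !"SE" %in% colnames(de))
    stop(what, " lacks an 'SE' column; supply replicate-level input or a ",
         "table from simulateDEExperiment(), which computes per-gene SEs",
         call. = FALSE)
  if (anyDuplicated(de$gene))
    stop(what, " has duplicated gene identifiers", call. = FALSE)
  invisible(de)
}

# Welch two-sample t on the rows of two matrices; returns lfc (meanA-meanB),
# pooled SE and two-sided p. Used by the generator and axis DE.
rowWelch <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  se <- sqrt(va / na + vb / nb)
  t <- (ma - mb) / se
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  data.frame(log2FC = ma - mb, SE = se, p = p)
}

# two-sided p for a Pearson correlation via the t transform
corPvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(abs(t), df = n - 2, lower.tail = FALSE)
}

# deterministic child seeds so one user seed drives many generators
childSeed <- function(seed, k) {
  (as.integer(seed) * 1103L + as.integer(k) * 12347L) %% .Machine$integer.max
}
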