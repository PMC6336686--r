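#' Tumor-versus-normal Z-score transformation
#'
#' Standardizes each gene's tumor expression against the normal-sample
#' reference: `Z[g, s] = (x[g, s] - mean_normals(g)) / sd_normals(g)`.
#' Genes whose normal-reference SD is zero yield undefined scores; they
#' are flagged and should be excluded downstream.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param clinical data.frame with columns `sample` and `role`
#'   (`"tumor"`/`"normal"`), e.g. from [clinicalTable()].
#' @return list with `z` (genes x tumors Z matrix), `flagged` (gene ids
#'   with zero normal variance; their rows are NA), and the reference
#'   `normalMean`/`normalSd` vectors.
#' @examples
#' sc <- simulateCohort(cohortSpec(nTumors = 20, nNormals = 5,
#'                                 nGenes = 10, nMirnas = 2, seed = 1))
#' z <- tumorNormalZ(geneExpr(sc), clinicalTable(sc))
#' dim(z$z)
#' @export
tumorNormalZ <- function(expr, clinical) {
  if (!all(c("sample", "role") %in% colnames(clinical)))
    stop("'clinical' needs columns 'sample' and 'role'", call. = FALSE)
  normals <- clinical$sample[clinical$role == "normal"]
  tumors <- clinical$sample[clinical$role == "tumor"]
  if (length(normals) < 2L)
    stop("at least 2 normal samples are required for a Z reference",
         call. = FALSE)
  if (!all(c(normals, tumors) %in% colnames(expr)))
    stop("clinical samples missing from the expression matrix", call. = FALSE)
  nm <- rowMeans(expr[, normals, drop = FALSE])
  ns <- apply(expr[, normals, drop = FALSE], 1L, sd)
  flagged <- rownames(expr)[ns == 0]
  ns[ns == 0] <- NA_real_
  z <- (expr[, tumors, drop = FALSE] - nm) / ns
  list(z = z, flagged = flagged, normalMean = nm, normalSd = ns)
}

#' Filter genes altered beyond a Z threshold in a minimum tumor fraction
#'
#' Keeps genes whose |Z| exceeds `zAbsMin` in strictly more than
#' `tumorFractionMin` of tumors — the outlier screen used to reduce a
#' cohort to its most distorted genes. Both comparisons are strict, so a
#' gene altered in exactly the threshold fraction is excluded.
#'
#' @param z genes x tumors Z matrix (or the list from [tumorNormalZ()]).
#' @param zAbsMin |Z| threshold, strict (default 2).
#' @param tumorFractionMin minimum tumor fraction, strict (default 0.35;
#'   a stricter screen uses 0.45).
#' @return character vector of retained gene ids.
#' @export
filterOutlierGenes <- function(z, zAbsMin = 2, tumorFractionMin = 0.35) {
  if (is.list(z) && !is.null(z$z)) z <- z$z
  if (zAbsMin <= 0 || tumorFractionMin <= 0)
    stop("'zAbsMin' and 'tumorFractionMin' must be > 0", call. = FALSE)
  if (is.null(rownames(z))) rownames(z) <- as.character(seq_len(nrow(z)))
  frac <- rowMeans(abs(z) > zAbsMin, na.rm = FALSE)
  frac[is.na(frac)] <- -Inf        # flagged zero-variance genes never pass
  rownames(z)[frac > tumorFractionMin]
}

#' Hierarchically cluster tumors and test the clinical association
#'
#' Agglomerative clustering of tumors on a filtered gene panel (genes
#' standardized, Euclidean distance, Ward linkage by default), followed by
#' two association tests of cluster membership against high Gleason grade
#' (sum > 7): an unadjusted chi-squared test, and an age-adjusted logistic
#' regression (likelihood-ratio test of cluster labels over the age-only
#' model). Both are reported because "adjusting for age" and a chi-squared
#' statistic cannot be combined in one test.
#'
#' @param expr genes x tumors matrix restricted to the gene panel.
#' @param clinical clinical table with `sample`, `gleason_sum`, `age`.
#' @param nClusters number of clusters to cut (>= 2).
#' @param distance,linkage `stats::dist` method and `stats::hclust`
#'   linkage (defaults "euclidean", "ward.D2").
#' @param standardize center/scale each gene before clustering.
#' @return list with `labels` (named cluster vector), `chisq`
#'   (statistic, df, p), `logistic` (LRT statistic, df, p), and the
#'   `hclust` tree.
#' @export
clusterAndAssociate <- function(expr, clinical, nClusters,
                                distance = "euclidean",
                                linkage = "ward.D2",
                                standardize = TRUE) {
  if (nClusters < 2L)
    stop("'nClusters' must be at least 2", call. = FALSE)
  if (nClusters > ncol(expr))
    stop("'nClusters' exceeds the number of samples", call. = FALSE)
  m <- expr
  if (standardize) {
    s <- apply(m, 1L, sd)
    m <- (m - rowMeans(m)) / ifelse(s == 0, 1, s)
  }
  tree <- hclust(dist(t(m), method = distance), method = linkage)
  labels <- cutree(tree, k = nClusters)

  cl <- clinical[match(colnames(expr), clinical$sample), ]
  highGleason <- cl$gleason_sum > 7
  ok <- !is.na(highGleason)
  chis <- suppressWarnings(chisq.test(table(labels[ok], highGleason[ok])))
  fit0 <- glm(highGleason[ok] ~ cl$age[ok], family = binomial())
  fit1 <- glm(highGleason[ok] ~ cl$age[ok] + factor(labels[ok]),
              family = binomial())
  lrt <- anova(fit0, fit1, test = "Chisq")
  list(labels = labels,
       chisq = list(statistic = unname(chis$statistic),
                    df = unname(chis$parameter), p = chis$p.value),
       logistic = list(deviance = lrt$Deviance[2], df = lrt$Df[2],
                       p = lrt$`Pr(>Chi)`[2]),
       tree = tree)
}

#' Screen genes or clusters for disease-free-survival association
#'
#' Per-gene mode splits tumors at the cohort median (or quartiles) of each
#' gene's expression and compares arms; per-cluster mode compares supplied
#' cluster labels. Each unit gets a log-rank p and a Cox hazard ratio with
#' 95\% CI (optionally age-adjusted); per-gene p-values are BH-adjusted.
#' Units where the model is inestimable (an empty arm, or no events) are
#' flagged rather than raising an error. Kaplan-Meier coordinates are
#' returned for plotting.
#'
#' @param x genes x tumors expression matrix (`mode = "per_gene"`), or a
#'   named vector of cluster labels (`mode = "per_cluster"`).
#' @param clinical clinical table with `sample`, `dfs_time`, `dfs_event`
#'   (and `age` if `adjustAge`).
#' @param mode `"per_gene_median_split"` or `"per_cluster"`.
#' @param padjMax BH-adjusted log-rank threshold for flagging hits
#'   (default 0.1).
#' @param split `"median"` or `"quartile"` (upper vs lower quartile arms).
#' @param adjustAge include age as a Cox covariate.
#' @param horizon optional truncation time in months (e.g. 60 for 5-year
#'   recurrence); events beyond it are censored at the horizon.
#' @return list with `results` (data.frame: unit, n, n_events, logrank_p,
#'   hr, hr_lo, hr_hi, cox_p, padj, significant, inestimable) and `km`
#'   (list of per-unit Kaplan-Meier coordinate data.frames).
#' @export
survivalScreen <- function(x, clinical,
                           mode = c("per_gene_median_split", "per_cluster"),
                           padjMax = 0.1, split = c("median", "quartile"),
                           adjustAge = FALSE, horizon = NULL) {
  mode <- match.arg(mode)
  split <- match.arg(split)
  need <- c("sample", "dfs_time", "dfs_event")
  if (!all(need %in% colnames(clinical)))
    stop("'clinical' needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  cl <- clinical[!is.na(clinical$dfs_time) & !is.na(clinical$dfs_event), ]
  time <- cl$dfs_time; event <- cl$dfs_event
  if (!is.null(horizon)) {
    event <- ifelse(time > horizon, 0L, event)
    time <- pmin(time, horizon)
  }

  groupsFor <- function(unit) {
    if (mode == "per_cluster") return(factor(x[cl$sample]))
    v <- x[unit, cl$sample]
    if (split == "median") {
      factor(ifelse(v > median(v), "high", "low"), c("low", "high"))
    } else {
      q <- quantile(v, c(0.25, 0.75))
      g <- rep(NA_character_, length(v))
      g[v <= q[1]] <- "low"; g[v >= q[2]] <- "high"
      factor(g, c("low", "high"))
    }
  }
  units <- if (mode == "per_cluster") "cluster" else rownames(x)

  one <- function(unit) {
    g <- groupsFor(unit)
    keep <- !is.na(g)
    gi <- droplevels(g[keep]); ti <- time[keep]; ei <- event[keep]
    bad <- nlevels(gi) < 2L || any(table(gi) < 2L) ||
      sum(ei) < 1L || any(tapply(ei, gi, sum) < 1L)
    if (bad)
      return(data.frame(unit = unit, n = sum(keep), n_events = sum(ei),
                        logrank_p = NA_real_, hr = NA_real_,
                        hr_lo = NA_real_, hr_hi = NA_real_,
                        cox_p = NA_real_, inestimable = TRUE))
    s <- survival::Surv(ti, ei)
    lr <- survival::survdiff(s ~ gi)
    lrp <- stats::pchisq(lr$chisq, df = length(lr$n) - 1L,
                         lower.tail = FALSE)
    fml <- if (adjustAge) s ~ gi + age else s ~ gi
    dat <- data.frame(gi = gi, age = cl$age[keep])
    cox <- survival::coxph(fml, data = dat)
    sm <- summary(cox)
    data.frame(unit = unit, n = sum(keep), n_events = sum(ei),
               logrank_p = lrp,
               hr = sm$conf.int[1, "exp(coef)"],
               hr_lo = sm$conf.int[1, "lower .95"],
               hr_hi = sm$conf.int[1, "upper .95"],
               cox_p = sm$coefficients[1, "Pr(>|z|)"],
               inestimable = FALSE)
  }
  res <- do.call(rbind, lapply(units, one))
  res$padj <- if (mode == "per_cluster") res$logrank_p
              else p.adjust(res$logrank_p, "BH")
  res$significant <- !res$inestimable & !is.na(res$padj) & res$padj < padjMax

  km <- lapply(setNames(units, units), function(unit) {
    g <- groupsFor(unit)
    keep <- !is.na(g)
    if (sum(keep) < 2L || nlevels(droplevels(g[keep])) < 2L) return(NULL)
    fit <- survival::survfit(survival::Surv(time[keep], event[keep]) ~
                               droplevels(g[keep]))
    data.frame(time = fit$time, surv = fit$surv,
               arm = rep(sub("^.*=", "", names(fit$strata)), fit$strata))
  })
  list(results = res, km = km)
}
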