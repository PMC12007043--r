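#' Relative trait values under stress
#'
#' For every accession x trait x stress treatment x environment cell,
#' computes the trait relative value TR = Xd / Xc, the ratio of the
#' replicate-mean under the stress treatment (Xd) to the replicate-mean
#' under the well-watered control (Xc).
#'
#' Cells whose control mean is zero are flagged `undefined` and carry
#' `NA` ratios; a message reports how many were excluded.
#'
#' @param pheno long-format phenotype data.frame (columns `accession`,
#'   `trait`, `treatment`, `environment`, `replicate`, `value`).
#' @param control_code treatment code of the control (default `"CK"`).
#' @return data.frame with columns `accession`, `trait`, `treatment`,
#'   `environment`, `TR`, `undefined`.
#' @export
relative_trait <- function(pheno, control_code = "CK") {
  stopifnot(is.data.frame(pheno),
            all(c("accession", "trait", "treatment", "environment",
                  "value") %in% names(pheno)))
  if (!control_code %in% pheno$treatment) {
    stop("control treatment '", control_code, "' absent from the table",
         call. = FALSE)
  }
  agg <- stats::aggregate(value ~ accession + trait + treatment + environment,
                          data = pheno, FUN = mean)
  ctrl <- agg[agg$treatment == control_code, ]
  strs <- agg[agg$treatment != control_code, ]
  key <- function(d) paste(d$accession, d$trait, d$environment, sep = "\r")
  idx <- match(key(strs), key(ctrl))
  if (anyNA(idx)) {
    stop("some stress cells lack a matching control cell", call. = FALSE)
  }
  xc <- ctrl$value[idx]
  undefined <- xc == 0
  tr <- ifelse(undefined, NA_real_, strs$value / xc)
  if (any(undefined)) {
    message(sum(undefined),
            " cell(s) had a zero control mean; TR flagged undefined")
  }
  data.frame(accession = strs$accession, trait = strs$trait,
             treatment = strs$treatment, environment = strs$environment,
             TR = tr, undefined = undefined, stringsAsFactors = FALSE)
}

#' Drought tolerance index
#'
#' Computes, per accession, a yield-based stress index from the panel's
#' yield under drought (YD) and under normal irrigation (YP). Two readings
#' of the index are available:
#' \describe{
#'   \item{`"ratio"` (default)}{`DI = (YD / YP) * (YD / mean(YD))` -
#'     dimensionless, the stress-susceptibility ratio weighted by the
#'     accession's drought yield relative to the panel mean.}
#'   \item{`"literal"`}{`DI = (YD / YP) * mean(YD)` - the ratio scaled by
#'     the panel-mean drought yield (carries yield units).}
#' }
#'
#' @param pheno long-format phenotype data.frame.
#' @param yield_trait trait name holding yield (default `"yield"`).
#' @param stress_code,control_code treatment codes for drought and control.
#' @param di_formula `"ratio"` or `"literal"` (see Details).
#' @return data.frame with columns `accession`, `YD`, `YP`, `DI`,
#'   `undefined` (TRUE where `YP` is zero).
#' @export
drought_tolerance_index <- function(pheno, yield_trait = "yield",
                                    stress_code = "S", control_code = "CK",
                                    di_formula = c("ratio", "literal")) {
  di_formula <- match.arg(di_formula)
  sub <- pheno[pheno$trait == yield_trait &
                 pheno$treatment %in% c(stress_code, control_code), ]
  if (!nrow(sub)) stop("no yield rows for the requested treatments",
                       call. = FALSE)
  agg <- stats::aggregate(value ~ accession + treatment, data = sub,
                          FUN = mean)
  yd <- agg[agg$treatment == stress_code, ]
  yp <- agg[agg$treatment == control_code, ]
  idx <- match(yd$accession, yp$accession)
  if (anyNA(idx)) stop("accessions missing control yield", call. = FALSE)
  YD <- yd$value
  YP <- yp$value[idx]
  ydbar <- mean(YD)
  if (ydbar == 0) stop("panel-mean drought yield is zero; DI undefined",
                       call. = FALSE)
  undefined <- YP == 0
  di <- switch(di_formula,
               ratio = (YD / YP) * (YD / ydbar),
               literal = (YD / YP) * ydbar)
  di[undefined] <- NA_real_
  data.frame(accession = yd$accession, YD = YD, YP = YP, DI = di,
             undefined = undefined, stringsAsFactors = FALSE)
}

#' Composite indicators and factor weights by PCA
#'
#' Runs a principal-component analysis of the standardized indicator matrix
#' (accessions x indicators). Components are retained until their
#' cumulative explained variance reaches `cum_var` (at least one). The
#' retained component scores are the composite indicators Xi; each
#' component's explained-variance proportion is its contribution rate Pi,
#' and the factor weights are `w_i = P_i / sum(P_i)`, so the weights sum
#' to one.
#'
#' @param indicator_matrix numeric matrix or data.frame, accessions in rows
#'   (>= 3), indicators in columns (>= 2), no constant column.
#' @param cum_var cumulative explained-variance retention threshold,
#'   default 0.85.
#' @return list with `scores` (accessions x retained components),
#'   `weights`, `contribution` (Pi of retained components), `sdev` (all
#'   component standard deviations), `rotation`.
#' @export
composite_weights <- function(indicator_matrix, cum_var = 0.85) {
  X <- as.matrix(indicator_matrix)
  stopifnot(nrow(X) >= 3, ncol(X) >= 2, cum_var > 0, cum_var <= 1)
  if (anyNA(X)) stop("indicator matrix contains NA; drop or impute first",
                     call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant indicator column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  prop <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(prop) >= cum_var - 1e-12)[1]
  if (is.na(k)) k <- length(prop)
  k <- max(k, 1)
  Pi <- prop[seq_len(k)]
  w <- Pi / sum(Pi)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rotation <- pc$rotation
  # orient each retained component so it tracks overall performance:
  # indicators are larger-is-better, so align with the standardized row mean
  overall <- rowMeans(scale(X))
  for (j in seq_len(k)) {
    r <- stats::cor(scores[, j], overall)
    if (!is.na(r) && r < 0) {
      scores[, j] <- -scores[, j]
      rotation[, j] <- -rotation[, j]
    }
  }
  list(scores = scores, weights = w, contribution = Pi,
       sdev = pc$sdev, rotation = rotation)
}

#' Fuzzy membership values
#'
#' Min-max rescales each indicator across accessions:
#' `mu(Xi) = (Xi - Xi_min) / (Xi_max - Xi_min)`, so every indicator's
#' memberships span `[0, 1]`, attaining 0 at the panel minimum and 1 at the
#' panel maximum.
#'
#' @param scores accessions x indicators numeric matrix.
#' @return matrix of memberships, same shape as `scores`.
#' @export
membership <- function(scores) {
  X <- as.matrix(scores)
  rng <- apply(X, 2, range)
  flat <- rng[2, ] == rng[1, ]
  if (any(flat)) {
    stop("indicator(s) with max == min (membership undefined): ",
         paste(colnames(X)[flat] %||% which(flat), collapse = ", "),
         call. = FALSE)
  }
  sweep(sweep(X, 2, rng[1, ], "-"), 2, rng[2, ] - rng[1, ], "/")
}

#' Composite drought-tolerance D value
#'
#' Weighted sum of membership values, `D = sum_i mu(Xi) * w_i`, one value
#' per accession, guaranteed in `[0, 1]` when the weights sum to one.
#'
#' @param mu accessions x indicators membership matrix (values in `[0,1]`).
#' @param w weight vector summing to one (tolerance 1e-10).
#' @return named numeric vector of D values.
#' @export
d_value <- function(mu, w) {
  mu <- as.matrix(mu)
  if (ncol(mu) != length(w)) stop("weight/membership dimension mismatch",
                                  call. = FALSE)
  if (abs(sum(w) - 1) > 1e-10) stop("weights must sum to 1", call. = FALSE)
  if (any(mu < -1e-12 | mu > 1 + 1e-12)) {
    stop("membership values outside [0, 1]", call. = FALSE)
  }
  drop(mu %*% w)
}

#' Classify accessions into tolerance classes
#'
#' Agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distances) of the accession membership vectors, cut into `k` clusters.
#' Clusters are ranked by their mean D value and labelled from the most to
#' the least tolerant (for `k = 3`: `tolerant`, `medium`, `sensitive`).
#'
#' @param mu accessions x indicators membership matrix.
#' @param d per-accession D values (same order as `mu` rows).
#' @param k number of classes, default 3.
#' @return data.frame with columns `accession`, `D`, `class`, plus an
#'   attribute `degenerate` set when all D values tie.
#' @export
classify_accessions <- function(mu, d, k = 3) {
  mu <- as.matrix(mu)
  n <- nrow(mu)
  if (k > n) stop("k exceeds the number of accessions", call. = FALSE)
  acc <- rownames(mu) %||% as.character(seq_len(n))
  # order-invariant input: cluster on sorted accession ids, map back
  ord <- order(acc)
  hc <- stats::hclust(stats::dist(mu[ord, , drop = FALSE]), method = "ward.D2")
  cl_sorted <- stats::cutree(hc, k = k)
  cl <- integer(n)
  cl[ord] <- cl_sorted
  meanD <- tapply(d, cl, mean)
  rank_map <- rank(-meanD, ties.method = "first")
  labels3 <- c("tolerant", "medium", "sensitive")
  lab <- if (k == 3) labels3 else paste0("class", seq_len(k))
  class_lab <- lab[rank_map[as.character(cl)]]
  degenerate <- length(unique(d)) == 1
  if (degenerate) warning("all D values equal; classification is degenerate")
  out <- data.frame(accession = acc, D = d, class = class_lab,
                    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- degenerate
  out
}

#' Descriptive statistics of phenotypic traits
#'
#' Per trait x treatment x environment cell: mean, sample standard
#' deviation, max, min, adjusted Fisher-Pearson sample skewness, sample
#' excess kurtosis (both with the small-sample bias adjustments used by
#' common spreadsheet software), and the coefficient of variation
#' `CV = 100 * sd / mean`. Cells with fewer than 3 observations get `NA`
#' skewness/kurtosis with a warning.
#'
#' @param pheno long-format phenotype data.frame.
#' @return data.frame with one row per trait x treatment x environment.
#' @export
descriptive_stats <- function(pheno) {
  stopifnot(all(c("trait", "treatment", "environment", "value") %in%
                  names(pheno)))
  cells <- split(pheno$value,
                 list(pheno$trait, pheno$treatment, pheno$environment),
                 drop = TRUE)
  small <- 0L
  rows <- lapply(names(cells), function(nm) {
    v <- cells[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    n <- length(v)
    m <- mean(v)
    s <- stats::sd(v)
    if (n < 3) {
      small <<- small + 1L
      sk <- ku <- NA_real_
    } else {
      sk <- sample_skewness(v)
      ku <- sample_kurtosis(v)
    }
    data.frame(trait = parts[1], treatment = parts[2], environment = parts[3],
               n = n, mean = m, sd = s, max = max(v), min = min(v),
               skewness = sk, kurtosis = ku,
               cv = if (m != 0) 100 * s / m else NA_real_,
               stringsAsFactors = FALSE)
  })
  if (small > 0) warning(small, " cell(s) had < 3 observations; ",
                         "skewness/kurtosis omitted")
  out <- do.call(rbind, rows)
  out[order(out$trait, out$treatment, out$environment), ]
}

# adjusted Fisher-Pearson sample skewness: n/((n-1)(n-2)) * sum(((x-m)/s)^3)
sample_skewness <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0) return(0)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

# sample excess kurtosis with bias adjustment (spreadsheet KURT):
# n(n+1)/((n-1)(n-2)(n-3)) * sum(((x-m)/s)^4) - 3(n-1)^2/((n-2)(n-3))
sample_kurtosis <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0) return(0)
  if (n < 4) return(NA_real_)
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(((x - mean(x)) / s)^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

#' Full fuzzy-evaluation drought-tolerance scoring
#'
#' Convenience wrapper chaining the scoring steps: relative traits
#' averaged over environments per stress treatment, the drought-tolerance
#' index, PCA composite indicators and weights, membership values, the
#' composite D value, and the k-class tolerance classification.
#'
#' Accessions with missing indicator cells are dropped from the PCA with a
#' message (no imputation by default; `impute = "mean"` mean-fills instead).
#'
#' @param pheno long-format phenotype data.frame.
#' @param control_code control treatment code.
#' @param yield_trait trait used for the drought-tolerance index; set to
#'   `NULL` to omit DI from the indicator matrix.
#' @param di_formula passed to [drought_tolerance_index()].
#' @param traits traits entering the indicator matrix (default: all
#'   non-yield traits).
#' @param cum_var PCA retention threshold, see [composite_weights()].
#' @param k number of tolerance classes.
#' @param impute `"none"` (drop incomplete accessions) or `"mean"`.
#' @return list with `indicators`, `pca`, `mu`, `scores` (data.frame with
#'   accession, DI, D, class), `summary` (descriptive statistics),
#'   `relative` (the relative-trait table).
#' @export
score_drought_tolerance <- function(pheno, control_code = "CK",
                                    yield_trait = "yield",
                                    di_formula = "ratio",
                                    traits = NULL, cum_var = 0.85, k = 3,
                                    impute = c("none", "mean")) {
  impute <- match.arg(impute)
  rel <- relative_trait(pheno, control_code = control_code)
  rel_ok <- rel[!rel$undefined, ]
  if (is.null(traits)) {
    traits <- setdiff(unique(rel_ok$trait), yield_trait)
  }
  rel_use <- rel_ok[rel_ok$trait %in% traits, ]
  # average over environments; one indicator per trait x stress treatment
  agg <- stats::aggregate(TR ~ accession + trait + treatment, data = rel_use,
                          FUN = mean)
  agg$indicator <- paste(agg$trait, agg$treatment, sep = "_")
  wide <- stats::reshape(agg[, c("accession", "indicator", "TR")],
                         idvar = "accession", timevar = "indicator",
                         direction = "wide")
  names(wide) <- sub("^TR\\.", "", names(wide))
  rownames(wide) <- wide$accession
  ind <- as.matrix(wide[, -1, drop = FALSE])

  di <- NULL
  if (!is.null(yield_trait) && yield_trait %in% pheno$trait) {
    stress_codes <- setdiff(unique(pheno$treatment), control_code)
    di <- drought_tolerance_index(pheno, yield_trait = yield_trait,
                                  stress_code = stress_codes[length(stress_codes)],
                                  control_code = control_code,
                                  di_formula = di_formula)
    ind <- cbind(ind, DI = di$DI[match(rownames(ind), di$accession)])
  }

  complete <- stats::complete.cases(ind)
  if (!all(complete)) {
    if (impute == "mean") {
      cm <- colMeans(ind, na.rm = TRUE)
      na_idx <- which(is.na(ind), arr.ind = TRUE)
      ind[na_idx] <- cm[na_idx[, 2]]
      message(nrow(na_idx), " missing indicator cell(s) mean-imputed")
    } else {
      message(sum(!complete), " accession(s) dropped for missing indicators")
      ind <- ind[complete, , drop = FALSE]
    }
  }

  pca <- composite_weights(ind, cum_var = cum_var)
  mu <- membership(pca$scores)
  D <- d_value(mu, pca$weights)
  cls <- classify_accessions(mu, D, k = k)
  scores <- data.frame(accession = rownames(ind),
                       DI = if (is.null(di)) NA_real_ else
                         di$DI[match(rownames(ind), di$accession)],
                       D = D, class = cls$class, stringsAsFactors = FALSE)
  list(indicators = ind, pca = pca, mu = mu, scores = scores,
       summary = descriptive_stats(pheno), relative = rel)
}
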