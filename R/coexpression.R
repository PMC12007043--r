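#' Filter an expression matrix
#'
#' Keeps genes expressed at `min_fpkm` or above in at least `min_samples`
#' samples (defaults 1.0 FPKM in 3 samples).
#'
#' @param expr genes x samples non-negative matrix.
#' @param min_fpkm expression threshold (>= 0).
#' @param min_samples minimum number of samples meeting it.
#' @return the filtered matrix.
#' @export
filter_expression <- function(expr, min_fpkm = 1.0, min_samples = 3) {
  stopifnot(is.matrix(expr), min_fpkm >= 0, min_samples >= 0)
  keep <- rowSums(expr >= min_fpkm) >= min_samples
  if (!any(keep)) stop("every gene removed by the expression filter; ",
                       "lower min_fpkm or min_samples", call. = FALSE)
  expr[keep, , drop = FALSE]
}

#' Soft-threshold adjacency and topological overlap matrix
#'
#' Builds the weighted co-expression network: adjacency
#' `a_ij = |cor(x_i, x_j)|^beta` (unsigned, the default) or
#' `((1 + cor)/2)^beta` (signed), then the topological overlap
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_{u != i} a_iu`. TOM is symmetric, lies in
#' `[0, 1]`, and its diagonal is set to 1.
#'
#' @param expr genes x samples matrix; genes with zero variance must be
#'   removed beforehand.
#' @param power soft-threshold exponent beta (default 9).
#' @param network `"unsigned"` (default) or `"signed"`.
#' @return list with `adjacency` and `tom` (both genes x genes), and the
#'   correlation matrix `cor`.
#' @export
adjacency_tom <- function(expr, power = 9, network = c("unsigned",
                                                       "signed")) {
  network <- match.arg(network)
  stopifnot(is.matrix(expr), ncol(expr) >= 3, power > 0)
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    stop("constant gene(s) reached the network stage: ",
         paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  cc <- stats::cor(t(expr))
  A <- switch(network,
              unsigned = abs(cc)^power,
              signed = ((1 + cc) / 2)^power)
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  dimnames(A) <- dimnames(tom) <- list(rownames(expr), rownames(expr))
  list(adjacency = A, tom = tom, cor = cc)
}

# conventional module color-name sequence, by descending module size
module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta")

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - TOM`, cut with a simplified dynamic procedure: candidate cut
#' heights (the dendrogram's merge heights) are scanned and the tree is
#' cut at the lowest height that maximizes the number of branches of at
#' least `min_module_size` genes; those branches become modules and all
#' remaining genes are assigned to `"grey"` (unassigned). A fixed
#' `cut_height` can be supplied to override the scan. Modules whose
#' eigengenes correlate above `1 - merge_cut` are then merged
#' iteratively, and the final modules are named by size rank using the
#' conventional color sequence.
#'
#' @param tom_result result of [adjacency_tom()] (or a bare TOM matrix).
#' @param expr the expression matrix used to compute eigengenes for the
#'   merge step.
#' @param min_module_size minimum genes per module (default 50).
#' @param merge_cut eigengene-dissimilarity merge threshold (default 0.25:
#'   modules with eigengene correlation > 0.75 merge).
#' @param cut_height optional fixed tree-cut height on the 1 - TOM scale;
#'   `NULL` (default) selects the height adaptively as described above.
#' @return list with `modules` (named character vector gene -> color),
#'   `eigengenes` (modules x samples), `sizes`, `dendro` (the hclust
#'   object).
#' @export
detect_modules <- function(tom_result, expr, min_module_size = 50,
                           merge_cut = 0.25, cut_height = NULL) {
  tom <- if (is.list(tom_result)) tom_result$tom else tom_result
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom),
            nrow(tom) == nrow(expr))
  genes <- rownames(tom) %||% rownames(expr)
  n <- nrow(tom)
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  if (n < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    return(list(modules = stats::setNames(rep("grey", n), genes),
                eigengenes = NULL, sizes = c(grey = n), dendro = hc))
  }
  if (is.null(cut_height)) {
    # adaptive cut: the branch count that persists over the widest range of
    # merge heights is taken as the module count, and the tree is cut at
    # the top of that count's longest plateau (so every module is fully
    # assembled before unrelated genes start joining)
    root <- max(hc$height)
    hs <- sort(unique(hc$height))
    hs <- hs[hs < root]  # cutting at the root yields one trivial branch
    if (!length(hs)) hs <- root / 2
    cuts <- as.matrix(stats::cutree(hc, h = hs))
    n_big <- apply(cuts, 2, function(cl) sum(table(cl) >= min_module_size))
    iv <- diff(c(hs, root))
    persist <- tapply(iv, n_big, sum)
    cand <- as.integer(names(persist))
    persist <- persist[cand >= 1]
    cand <- cand[cand >= 1]
    if (!length(cand)) {
      warning("no branch ever reaches min_module_size; all genes unassigned")
      return(list(modules = stats::setNames(rep("grey", n), genes),
                  eigengenes = NULL, sizes = c(grey = n), dendro = hc))
    }
    v_star <- cand[which.max(persist)]
    runs <- rle(n_big == v_star)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    span <- ifelse(runs$values,
                   vapply(seq_along(runs$values), function(i) {
                     sum(iv[starts[i]:ends[i]])
                   }, numeric(1)), -Inf)
    best <- which.max(span)
    cut_height <- hs[ends[best]]
  }
  raw <- stats::cutree(hc, h = cut_height)
  tab <- table(raw)
  keep <- names(tab)[tab >= min_module_size]
  lab <- ifelse(raw %in% as.integer(keep), as.character(raw), "grey")
  names(lab) <- genes

  # iterative eigengene-based merging of close modules
  repeat {
    mods <- setdiff(unique(lab), "grey")
    if (length(mods) < 2) break
    me <- t(vapply(mods, function(m) {
      eigengene(expr[lab == m, , drop = FALSE])
    }, numeric(ncol(expr))))
    cc <- stats::cor(t(me))
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) <= 1 - merge_cut) break
    lab[lab == mods[top[2]]] <- mods[top[1]]
  }

  mods <- setdiff(unique(lab), "grey")
  sizes <- sort(table(lab[lab != "grey"]), decreasing = TRUE)
  color_of <- stats::setNames(
    c(module_colors, paste0("module", seq_len(max(0, length(mods) -
                                                    length(module_colors)))))[
                                                      seq_along(sizes)],
    names(sizes))
  final <- ifelse(lab == "grey", "grey", color_of[lab])
  names(final) <- genes
  eg <- module_eigengenes(expr, final)
  list(modules = final, eigengenes = eg,
       sizes = sort(table(final), decreasing = TRUE), dendro = hc)
}

# first principal component of the standardized module expression, unit
# variance across samples, sign-aligned with the module mean profile
eigengene <- function(mexpr) {
  if (nrow(mexpr) == 1) {
    z <- drop(scale(mexpr[1, ]))
    return(z / stats::sd(z))
  }
  Z <- t(scale(t(mexpr)))
  Z <- Z[apply(mexpr, 1, stats::sd) > 0, , drop = FALSE]
  if (!nrow(Z)) return(rep(0, ncol(mexpr)))
  pc <- stats::prcomp(t(Z), center = FALSE, scale. = FALSE)
  e <- pc$x[, 1]
  e <- e / stats::sd(e)
  if (stats::cor(e, colMeans(Z)) < 0) e <- -e
  e
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression submatrix, rescaled to unit variance across
#' samples and sign-aligned so it correlates positively with the module's
#' mean expression profile. A single-gene module's eigengene is that
#' gene's standardized profile.
#'
#' @param expr genes x samples matrix.
#' @param modules named character vector gene -> module label; `"grey"`
#'   genes are skipped.
#' @return modules x samples numeric matrix.
#' @export
module_eigengenes <- function(expr, modules) {
  stopifnot(length(modules) == nrow(expr))
  mods <- setdiff(unique(modules), "grey")
  if (!length(mods)) return(NULL)
  eg <- t(vapply(mods, function(m) {
    eigengene(expr[modules == m, , drop = FALSE])
  }, numeric(ncol(expr))))
  rownames(eg) <- mods
  colnames(eg) <- colnames(expr)
  eg
}

#' Module-trait correlation table
#'
#' Pearson correlation of each module eigengene with each numeric sample
#' covariate, with p-values from the exact t transform on `n - 2` degrees
#' of freedom and the conventional significance stars (`*`, `**`, `***`
#' at 0.05, 0.01, 0.001).
#'
#' @param eigengenes modules x samples matrix.
#' @param sample_traits data.frame or matrix of numeric covariates, one
#'   row per sample (binary treatment indicators are typical).
#' @return data.frame with columns `module`, `trait`, `r`, `p`, `stars`.
#' @export
module_trait_correlation <- function(eigengenes, sample_traits) {
  st <- as.data.frame(sample_traits)
  stopifnot(nrow(st) == ncol(eigengenes), ncol(eigengenes) >= 3)
  keep <- vapply(st, function(v) is.numeric(v) && stats::sd(v) > 0,
                 logical(1))
  if (!all(keep)) {
    warning("skipping zero-variance or non-numeric covariate(s): ",
            paste(names(st)[!keep], collapse = ", "))
  }
  st <- st[, keep, drop = FALSE]
  if (!ncol(st)) {
    return(data.frame(module = character(), trait = character(),
                      r = numeric(), p = numeric(), stars = character(),
                      stringsAsFactors = FALSE))
  }
  n <- ncol(eigengenes)
  grid <- expand.grid(module = rownames(eigengenes), trait = names(st),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r <- mapply(function(m, tr) stats::cor(eigengenes[m, ], st[[tr]]),
              grid$module, grid$trait)
  p <- cor_pvalue(r, n)
  data.frame(grid, r = r, p = p, stars = significance_stars(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group differential expression (simple stand-in)
#'
#' A deliberately simple two-group caller: per gene, the log2 fold change
#' of group means on the `log2(FPKM + 1)` scale, a Welch two-sample test,
#' and Benjamini-Hochberg adjustment. A gene is flagged differentially
#' expressed when `|log2FC| > min_log2fc` and the adjusted p-value is
#' below `max_q`. This is a linear-model surrogate for count-based
#' negative-binomial callers and is intended for the package's simulated
#' FPKM matrices, not for raw RNA-seq counts.
#'
#' @param expr genes x samples non-negative matrix.
#' @param group_a,group_b character vectors of sample (column) names, at
#'   least 2 each.
#' @param min_log2fc absolute log2 fold-change threshold (default 2).
#' @param max_q BH-adjusted p-value threshold (default 0.01).
#' @return data.frame with columns `gene`, `mean_a`, `mean_b`, `log2fc`,
#'   `p`, `q`, `de`, `direction`.
#' @export
differential_expression <- function(expr, group_a, group_b,
                                    min_log2fc = 2, max_q = 0.01) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2,
            all(c(group_a, group_b) %in% colnames(expr)))
  la <- log2(expr[, group_a, drop = FALSE] + 1)
  lb <- log2(expr[, group_b, drop = FALSE] + 1)
  ma <- rowMeans(la)
  mb <- rowMeans(lb)
  lfc <- ma - mb
  va <- apply(la, 1, stats::var)
  vb <- apply(lb, 1, stats::var)
  na_ <- ncol(la)
  nb_ <- ncol(lb)
  sed <- sqrt(va / na_ + vb / nb_)
  tstat <- (ma - mb) / sed
  df <- (va / na_ + vb / nb_)^2 /
    ((va / na_)^2 / (na_ - 1) + (vb / nb_)^2 / (nb_ - 1))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p[sed == 0 & lfc == 0] <- 1
  p[sed == 0 & lfc != 0] <- 0
  q <- stats::p.adjust(p, method = "BH")
  de <- abs(lfc) > min_log2fc & q < max_q & !is.na(q)
  data.frame(gene = rownames(expr), mean_a = ma, mean_b = mb, log2fc = lfc,
             p = p, q = q, de = de,
             direction = ifelse(lfc > 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}
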