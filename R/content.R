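#' Construct a presence/absence matrix
#'
#' @param m binary matrix, genomes x gene families, with row and column
#'   names.
#' @param groups named character vector mapping genome id to group label.
#' @export
pa_matrix <- function(m, groups = NULL) {
  if (!all(m %in% c(0, 1))) stop("entries must be 0/1")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("unique genome ids required")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("unique gene-family ids required")
  structure(m, groups = groups[rownames(m)],
            class = c("pa_matrix", "matrix", "array"))
}

#' Manhattan distance between genome gene contents
#'
#' `d(i, j) = sum_g |x_ig - x_jg|`: the count of gene families present in
#' exactly one of the two genomes — the metabolic-dissimilarity metric.
#'
#' @param pa a [pa_matrix] (or plain binary matrix).
#' @return symmetric distance matrix with zero diagonal.
#' @export
manhattan_matrix <- function(pa) {
  if (nrow(pa) == 0 || ncol(pa) == 0) stop("empty matrix")
  as.matrix(dist(unclass(pa), method = "manhattan"))
}

#' MinHash (mash) distance matrix
#'
#' Bottom-s MinHash sketches of canonical k-mers per sequence; pairwise
#' Jaccard estimated from the merged sketch, mapped to a distance by the
#' mash formula `d = -log(2j / (1 + j)) / k`. A zero Jaccard (disjoint
#' sketches) is capped at `max_dist`.
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param k k-mer size (default 21, the conventional genome-sketching
#'   choice).
#' @param sketch_size bottom-sketch size (default 1000).
#' @param seed hash seed (sketches are deterministic given k, sketch size
#'   and seed).
#' @param max_dist distance assigned to sketch-disjoint pairs.
#' @return symmetric distance matrix.
#' @export
mash_matrix <- function(seqs, k = 21, sketch_size = 1000, seed = 42,
                        max_dist = 1) {
  if (any(nchar(seqs) < k)) stop("k larger than a sequence")
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("g", seq_len(n))
  sketches <- lapply(seqs, cpp_minhash_sketch, k = k,
                     sketch_size = sketch_size, seed = as.integer(seed))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    jac <- cpp_sketch_jaccard(sketches[[i]], sketches[[j]], sketch_size)
    d[i, j] <- d[j, i] <- if (jac <= 0) max_dist else
      min(max_dist, -log(2 * jac / (1 + jac)) / k)
  }
  d
}

#' MinHash Jaccard estimate between two sequences
#'
#' @inheritParams mash_matrix
#' @param a,b nucleotide sequences.
#' @export
minhash_jaccard <- function(a, b, k = 21, sketch_size = 1000, seed = 42) {
  cpp_sketch_jaccard(cpp_minhash_sketch(a, k, sketch_size, as.integer(seed)),
                     cpp_minhash_sketch(b, k, sketch_size, as.integer(seed)),
                     sketch_size)
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimized by iterative majorization with monotone
#' regression (vegan's engine), seeded for reproducibility.
#'
#' @param d distance matrix (or dist).
#' @param dims embedding dimension.
#' @param seed RNG seed for the embedding.
#' @return list with `points` (items x dims), `stress` (0..1 scale) and
#'   `converged`.
#' @export
nmds_embed <- function(d, dims = 2, seed = 1) {
  dm <- as.dist(d)
  if (attr(dm, "Size") < dims + 1) stop("need at least dims + 1 items")
  set.seed(seed)
  fit <- vegan::monoMDS(dm, k = dims, model = "global")
  converged <- fit$icause %in% c(1, 2)   # stress ratio / minimum stress met
  if (!converged)
    warning("NMDS did not converge after ", fit$iters, " iterations; ",
            "final stress ", signif(fit$stress, 4))
  pts <- fit$points
  rownames(pts) <- attr(dm, "Labels")
  list(points = pts, stress = fit$stress, converged = converged)
}

#' Kruskal stress-1 of a configuration
#'
#' Monotone (isotonic) regression of the configuration distances on the
#' dissimilarity ranks; stress-1 = sqrt(sum (dhat - fitted)^2 / sum
#' dhat^2). Invariant to rotation, translation and uniform scaling of the
#' configuration.
#'
#' @param d dissimilarity matrix.
#' @param coords configuration (items x dims).
#' @export
kruskal_stress <- function(d, coords) {
  dv <- as.vector(as.dist(d))
  conf <- as.vector(dist(coords))
  ord <- order(dv, conf)
  iso <- stats::isoreg(seq_along(ord), conf[ord])
  sqrt(sum((conf[ord] - iso$yf)^2) / sum(conf^2))
}

#' Normalized-dissimilarity convergence permutation test
#'
#' Tests whether two groups are closer in metabolic (gene-content) space
#' than in nucleotide space: both matrices are z-normalized over their
#' off-diagonal entries, the statistic is `T = mean normalized met distance
#' over A x B pairs - mean normalized nuc distance over A x B pairs`, and
#' the null distribution permutes genome identities jointly in both
#' matrices (preserving each matrix's internal structure while breaking the
#' group-metric linkage). One-sided add-one p-value: small T (metabolically
#' closer than expected) is the convergence signal.
#'
#' @param met,nuc distance matrices over the same genome ids.
#' @param groupA,groupB disjoint character vectors of genome ids.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @param normalize `"zscore"` (default) or `"rank"`.
#' @return list with `statistic`, `p_value`, `n_perm`, `perm_stats`.
#' @export
convergence_permutation_test <- function(met, nuc, groupA, groupB,
                                         n_perm = 999, seed = 1,
                                         normalize = c("zscore", "rank")) {
  normalize <- match.arg(normalize)
  ids <- rownames(met)
  if (!identical(sort(ids), sort(rownames(nuc))))
    stop("matrices must share the same id set")
  nuc <- nuc[ids, ids]
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  if (!length(groupA) || !length(groupB)) stop("groups must be non-empty")
  if (!all(c(groupA, groupB) %in% ids)) stop("unknown genome ids in groups")
  if (n_perm < 99) stop("n_perm must be >= 99")
  znorm <- function(m) {
    off <- m[lower.tri(m) | upper.tri(m)]
    if (normalize == "zscore") (m - mean(off)) / sd(off)
    else matrix(rank(m), nrow(m)) / length(m)   # rank normalization
  }
  mz <- znorm(met); nz <- znorm(nuc)
  ia <- match(groupA, ids); ib <- match(groupB, ids)
  stat <- function(a, b) mean(mz[a, b]) - mean(nz[a, b])
  t_obs <- stat(ia, ib)
  set.seed(seed)
  t_perm <- numeric(n_perm)
  n <- length(ids)
  for (p in seq_len(n_perm)) {
    pi <- sample.int(n)
    t_perm[p] <- stat(pi[ia], pi[ib])
  }
  p_val <- (sum(t_perm <= t_obs) + 1) / (n_perm + 1)
  list(statistic = t_obs, p_value = p_val, n_perm = n_perm,
       perm_stats = t_perm)
}

#' Phylogenetic signal of a trait (Pagel's lambda)
#'
#' Maximum-likelihood lambda under a Brownian model on the
#' lambda-transformed covariance, with a likelihood-ratio p-value against
#' lambda = 0 (phytools' phylosig engine). Binary presence/absence traits
#' are handled as 0/1 continuous values — a pragmatic, widely used reading;
#' see the methods vignette for the caveat. A star tree (lambda
#' unidentifiable) returns NA with a note.
#'
#' @param tree a [timetree] (tips = genomes).
#' @param trait named numeric (or 0/1) vector over the tips.
#' @return list with `lambda`, `logL`, `logL0`, `p`.
#' @export
phylo_signal <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait must be named by tip")
  trait <- trait[tree$tip.label]
  if (anyNA(trait)) stop("trait missing for some tips")
  if (var(trait) == 0) stop("trait variance must be > 0")
  res <- tryCatch(
    phytools::phylosig(tree, trait, method = "lambda", test = TRUE),
    error = function(e) NULL)
  if (is.null(res))
    return(list(lambda = NA_real_, logL = NA_real_, logL0 = NA_real_,
                p = NA_real_, note = "lambda unidentifiable (star-like tree)"))
  list(lambda = unname(res$lambda), logL = unname(res$logL),
       logL0 = unname(res$logL0), p = unname(res$P))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone, clipped at 1).
#'
#' @param pvals p-values in [0, 1].
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p outside [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Gene association battery
#'
#' For each gene family and each group contrast: a two-sided Fisher's exact
#' test of presence against membership, the Pearson correlation between the
#' gene's column and the focal gene's column, and the phylogenetic-signal
#' test of the gene on the dated tree. P-values are Benjamini-Hochberg
#' corrected within each test family (across genes, per contrast); a gene
#' passes when its adjusted p < `alpha`.
#'
#' @param pa a [pa_matrix] with a `groups` attribute.
#' @param tree tree over the genomes (for the phylogenetic-signal test);
#'   `NULL` skips that test.
#' @param contrasts named list; each element is `list(groups_in = <labels
#'   counting as members>, groups = <labels defining the genome universe of
#'   the contrast>)` (absent `groups` means all genomes).
#' @param focal_gene column name of the focal gene (the ammonia-oxidation
#'   marker analog).
#' @param genes columns to test (default: all but the focal gene).
#' @param alpha pass threshold on adjusted p.
#' @return data.frame of `AssociationRecord`s.
#' @export
association_battery <- function(pa, tree = NULL, contrasts, focal_gene,
                                genes = NULL, alpha = 0.05) {
  groups <- attr(pa, "groups")
  if (is.null(groups)) stop("pa matrix lacks group labels")
  if (!focal_gene %in% colnames(pa)) stop("unknown focal gene")
  if (is.null(genes)) genes <- setdiff(colnames(pa), focal_gene)
  out <- list()
  for (cname in names(contrasts)) {
    ct <- contrasts[[cname]]
    universe <- if (is.null(ct[["groups"]])) rownames(pa) else
      rownames(pa)[groups %in% ct[["groups"]]]
    if (!length(universe)) stop("contrast ", cname, " has an empty universe")
    member <- groups[universe] %in% ct[["groups_in"]]
    if (!any(member) || all(member))
      stop("contrast ", cname, " has an empty group")
    sub <- pa[universe, , drop = FALSE]
    subtree <- if (!is.null(tree)) ape::keep.tip(tree, universe) else NULL
    rec <- lapply(genes, function(g) {
      x <- sub[, g]
      tab <- table(factor(x, levels = 0:1), factor(member, levels = c(FALSE, TRUE)))
      ft <- fisher.test(tab)
      pr <- if (var(x) > 0 && var(sub[, focal_gene]) > 0)
        suppressWarnings(cor.test(x, sub[, focal_gene]))
      else list(estimate = NA_real_, p.value = NA_real_)
      ps <- if (!is.null(subtree) && var(x) > 0)
        phylo_signal(subtree, setNames(x, universe))
      else list(lambda = NA_real_, p = NA_real_)
      data.frame(gene = g, contrast = cname,
                 fisher_or = unname(ft$estimate), fisher_p = ft$p.value,
                 pearson_r = unname(pr$estimate), pearson_p = pr$p.value,
                 lambda = ps$lambda, phylosig_p = ps$p,
                 stringsAsFactors = FALSE)
    })
    rec <- do.call(rbind, rec)
    rec$fisher_p_adj <- bh_adjust(rec$fisher_p)
    rec$pearson_p_adj <- bh_adjust(rec$pearson_p)
    rec$phylosig_p_adj <- if (all(is.na(rec$phylosig_p))) NA_real_ else
      bh_adjust(rec$phylosig_p)
    rec$pass <- rec$fisher_p_adj < alpha
    out[[cname]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
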