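#' Delta-log-likelihood gene verticality score
#'
#' `delta LL = max_topology l(gene) - l(gene | species topology)`, each term
#' with branch lengths re-optimized under the same substitution model; a
#' vertically inherited gene scores near 0, a discordant (e.g. transferred)
#' gene scores high. The species topology is pruned to the gene's taxa and
#' unrooted (reversible models are root-invariant). Topology search is
#' exhaustive for <= 7 taxa and NNI hill-climbing otherwise.
#'
#' @param aln the gene [alignment].
#' @param species_tree rooted species topology containing the gene's taxa.
#' @param model a [subst_model].
#' @param search `"auto"`, `"exhaustive"` or `"nni"`.
#' @return class `delta_ll`: `delta_ll`, `ll_species`, `ll_best`,
#'   `best_tree`, `n_taxa`.
#' @export
compute_delta_ll <- function(aln, species_tree, model = subst_model("JC"),
                             search = c("auto", "exhaustive", "nni")) {
  search <- match.arg(search)
  taxa <- sort(intersect(aln$taxa, species_tree$tip.label))
  if (length(taxa) < length(aln$taxa))
    stop("gene taxa must be a subset of the species tree")
  if (length(taxa) < 4) stop("< 4 taxa: no alternative topologies")
  sp <- ape::unroot(ape::keep.tip(species_tree, taxa))
  sub <- subset_alignment(aln, intersect(aln$taxa, taxa))
  score <- function(top) {
    top$edge.length <- NULL
    # candidate topologies that fit the data badly routinely push a branch
    # to the bound; that is expected during search, not worth a warning
    suppressWarnings(optimize_branch_lengths(sub, top, model)$loglik)
  }
  ll_species <- score(sp)
  if (search == "auto") search <- if (length(taxa) <= 7) "exhaustive" else "nni"
  if (search == "exhaustive") {
    tops <- phangorn::allTrees(length(taxa), tip.label = taxa)
    lls <- vapply(tops, score, 0)
    best_i <- which.max(lls)
    ll_best <- lls[best_i]
    best_tree <- tops[[best_i]]
  } else {
    cur <- sp; ll_best <- ll_species; best_tree <- sp
    for (round in 1:20) {
      nbrs <- phangorn::nni(cur)
      lls <- vapply(nbrs, score, 0)
      i <- which.max(lls)
      if (lls[i] > ll_best + 1e-6) {
        ll_best <- lls[i]; cur <- nbrs[[i]]; best_tree <- cur
      } else break
    }
  }
  structure(list(delta_ll = max(0, ll_best - ll_species),
                 ll_species = ll_species, ll_best = ll_best,
                 best_tree = best_tree, n_taxa = length(taxa)),
            class = "delta_ll")
}

# delta LL for a gene list, ties broken by name for reproducible ordering
gene_dll_table <- function(genes, species_tree, model, search = "auto") {
  dll <- vapply(genes, function(g)
    compute_delta_ll(g, species_tree, model, search)$delta_ll, 0)
  df <- data.frame(gene = names(genes), dll = unname(dll),
                   stringsAsFactors = FALSE)
  df[order(-df$dll, df$gene), ]
}

#' Clade age gap
#'
#' `mean age(cladeB) - mean age(cladeA)` over the posterior draws of the
#' requested node (total group by default); negative means clade A is
#' older.
#'
#' @param posterior a `chrono_posterior`.
#' @param cladeA,cladeB [clade_ref]s (their `scope` is overridden by
#'   `scope`).
#' @param scope `"total"` or `"crown"`.
#' @return the gap in Ma.
#' @export
clade_age_gap <- function(posterior, cladeA, cladeB, scope = "total") {
  cladeA$scope <- scope; cladeB$scope <- scope
  mean(clade_ages(posterior, cladeB)) - mean(clade_ages(posterior, cladeA))
}

trajectory_row <- function(step, genes_kept, mean_dll, posterior, cladeA,
                           cladeB, scope) {
  aA <- clade_ages(posterior, within_scope(cladeA, scope))
  aB <- clade_ages(posterior, within_scope(cladeB, scope))
  hA <- hpd_interval(aA); hB <- hpd_interval(aB)
  data.frame(step = step, n_genes = length(genes_kept),
             genes_retained = paste(genes_kept, collapse = ","),
             mean_dll = mean_dll,
             ageA_mean = mean(aA), ageA_lo = hA[1], ageA_hi = hA[2],
             ageB_mean = mean(aB), ageB_lo = hB[1], ageB_hi = hB[2],
             age_gap = mean(aB) - mean(aA), stringsAsFactors = FALSE)
}

within_scope <- function(clade, scope) { clade$scope <- scope; clade }

#' Gene-removal screening trajectory
#'
#' Sorts gene families by delta LL (descending, ties by name), then
#' repeatedly removes the `step` most discordant genes, re-concatenates,
#' re-dates, and records the posterior ages of two tracked clades and their
#' age gap, until `floor` genes remain. The first record uses the full gene
#' set. Dating failures truncate the trajectory with a warning.
#'
#' @param genes named list of gene [alignment]s.
#' @param species_tree rooted species topology.
#' @param date_fn function `alignment -> chrono_posterior`.
#' @param cladeA,cladeB tracked [clade_ref]s.
#' @param step genes removed per iteration.
#' @param floor stop when this many genes remain.
#' @param scope clade scope for the recorded ages.
#' @param model substitution model for the delta LL scores.
#' @param dll optional precomputed table from `gene_dll_table`.
#' @return a `screening_trajectory` data.frame (one row per dating step).
#' @export
gene_removal_series <- function(genes, species_tree, date_fn, cladeA, cladeB,
                                step = 2, floor = 6, scope = "total",
                                model = subst_model("JC"), dll = NULL) {
  if (length(genes) < step + floor)
    stop("need at least step + floor genes")
  if (is.null(dll)) dll <- gene_dll_table(genes, species_tree, model)
  order_desc <- dll$gene            # most discordant first
  retained <- order_desc
  out <- list(); k <- 0
  repeat {
    aln <- concat_alignments(genes[retained])
    post <- tryCatch(date_fn(aln), error = function(e) e)
    if (inherits(post, "error")) {
      warning("dating failed at step ", k, ": ", conditionMessage(post),
              "; trajectory truncated")
      break
    }
    mean_dll <- mean(dll$dll[dll$gene %in% retained])
    out[[length(out) + 1]] <- trajectory_row(k, retained, mean_dll, post,
                                             cladeA, cladeB, scope)
    if (length(retained) - step < floor) break
    retained <- retained[-seq_len(step)]   # drop the top `step` by delta LL
    k <- k + 1
  }
  traj <- do.call(rbind, out)
  class(traj) <- c("screening_trajectory", "data.frame")
  attr(traj, "mode") <- "removal"
  traj
}

#' Sliding-window screening trajectory
#'
#' Genes are sorted by delta LL (ascending: most vertical first); each
#' contiguous window of `k` genes is concatenated and dated, recording the
#' window's mean delta LL and the tracked clade ages — so the age gap can
#' be read against gene verticality at constant gene number. There are
#' `n - k + 1` windows at step size 1.
#'
#' @inheritParams gene_removal_series
#' @param k window size (the study's values: 6, 8, 10, 12; default 10).
#' @param step window step size.
#' @export
sliding_window_series <- function(genes, species_tree, date_fn, cladeA,
                                  cladeB, k = 10, step = 1, scope = "total",
                                  model = subst_model("JC"), dll = NULL) {
  if (k > length(genes)) stop("window size k exceeds the number of genes")
  if (is.null(dll)) dll <- gene_dll_table(genes, species_tree, model)
  order_asc <- dll$gene[order(dll$dll, dll$gene)]
  starts <- seq(1, length(genes) - k + 1, by = step)
  out <- list()
  for (i in seq_along(starts)) {
    win <- order_asc[starts[i]:(starts[i] + k - 1)]
    aln <- concat_alignments(genes[win])
    post <- tryCatch(date_fn(aln), error = function(e) e)
    if (inherits(post, "error")) {
      warning("dating failed at window ", i, ": ", conditionMessage(post),
              "; trajectory truncated")
      break
    }
    mean_dll <- mean(dll$dll[dll$gene %in% win])
    out[[length(out) + 1]] <- trajectory_row(i, win, mean_dll, post,
                                            cladeA, cladeB, scope)
  }
  traj <- do.call(rbind, out)
  class(traj) <- c("screening_trajectory", "data.frame")
  attr(traj, "mode") <- "window"
  traj
}

#' Plot a screening trajectory
#'
#' Age gap (and mean delta LL) against the screening step, mirroring the
#' gene-removal / sliding-window diagnostic figures.
#'
#' @param traj a `screening_trajectory`.
#' @export
plot_screening_trajectory <- function(traj) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 required for plotting")
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$mean_dll, y = .data$age_gap)) +
    ggplot2::geom_point() + ggplot2::geom_path(alpha = 0.5) +
    ggplot2::labs(x = "mean delta LL of retained genes", y = "age gap (Ma)")
}
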