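# Cross-species comparison: reciprocal-best-hit orthology constrained by
# locus position (the EDC is a tandem array of similar paralogs, so
# sequence similarity alone confounds paralogs -- shared synteny is part of
# the orthology call), per-species gene-family censuses, Dollo gain/loss
# histories on a fixed species tree, and a comparative locus map.

#' Reciprocal-best-hit orthologs with a synteny constraint
#'
#' A pair is orthologous iff each protein is the other's best global
#' alignment score and their locus ranks differ by at most
#' `max_rank_delta`. Score ties are broken by identity, then id order.
#'
#' @param proteins_a,proteins_b named character vectors of proteins, in
#'   locus order (names are gene ids).
#' @param scheme a [default_score_scheme()].
#' @param ranks_a,ranks_b optional integer locus ranks (default: position
#'   in the input vector).
#' @param max_rank_delta maximum difference in locus rank (default 3).
#' @return data.frame `gene_a`, `gene_b`, `rbh`, `rank_delta`, `identity`.
#' @export
reciprocal_best_hits <- function(proteins_a, proteins_b,
                                 scheme = default_score_scheme(),
                                 ranks_a = NULL, ranks_b = NULL,
                                 max_rank_delta = 3L) {
  if (length(proteins_a) == 0L || length(proteins_b) == 0L)
    stop("both protein sets must be non-empty")
  if (is.null(ranks_a)) ranks_a <- seq_along(proteins_a)
  if (is.null(ranks_b)) ranks_b <- seq_along(proteins_b)
  na <- length(proteins_a); nb <- length(proteins_b)
  score <- matrix(0L, na, nb)
  ident <- matrix(0, na, nb)
  for (i in seq_len(na))
    for (j in seq_len(nb)) {
      g <- global_align(proteins_a[[i]], proteins_b[[j]], scheme)
      score[i, j] <- g$score; ident[i, j] <- g$identity
    }
  pick_best <- function(scores, idents) {
    best <- which(scores == max(scores))
    if (length(best) > 1L)
      best <- best[order(-idents[best], best)]
    best[1]
  }
  best_ab <- vapply(seq_len(na), function(i)
    pick_best(score[i, ], ident[i, ]), integer(1))
  best_ba <- vapply(seq_len(nb), function(j)
    pick_best(score[, j], ident[, j]), integer(1))
  rows <- list()
  for (i in seq_len(na)) {
    j <- best_ab[i]
    if (best_ba[j] != i) next
    delta <- abs(ranks_a[i] - ranks_b[j])
    if (delta > max_rank_delta) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = names(proteins_a)[i], gene_b = names(proteins_b)[j],
      rbh = TRUE, rank_delta = as.integer(delta), identity = ident[i, j],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      rbh = logical(), rank_delta = integer(),
                      identity = numeric()))
  do.call(rbind, rows)
}

#' Assign genes to named families by best hit to exemplar proteins
#'
#' @param proteins named character vector of proteins to assign.
#' @param exemplars named character vector: one exemplar protein per
#'   family (names are family names).
#' @param scheme a [default_score_scheme()].
#' @param min_score minimum local alignment score; genes below it go to
#'   family `"unclassified"`, never dropped.
#' @return data.frame `gene`, `family`, `score`, `identity` (assignment
#'   scores are reported so borderline calls can be audited).
#' @export
assign_families <- function(proteins, exemplars,
                            scheme = default_score_scheme(),
                            min_score = 40L) {
  rows <- lapply(names(proteins), function(g) {
    hits <- lapply(names(exemplars), function(f)
      local_align(proteins[[g]], exemplars[[f]], scheme))
    sc <- vapply(hits, `[[`, numeric(1), "score")
    best <- order(-sc, names(exemplars))[1]
    if (sc[best] < min_score)
      data.frame(gene = g, family = "unclassified", score = sc[best],
                 identity = NA_real_, stringsAsFactors = FALSE)
    else
      data.frame(gene = g, family = names(exemplars)[best],
                 score = sc[best], identity = hits[[best]]$identity,
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-species, per-family gene census
#'
#' @param annotations named list (one element per species) of data.frames
#'   with columns `gene`, `family`, `status` (complete/partial/pseudogene).
#' @return object of class `family_census`: data.frame with `species`,
#'   `family`, `complete`, `partial`, `pseudogene` (every species-family
#'   pair present, zeros explicit).
#' @export
family_census <- function(annotations) {
  stopifnot(is.list(annotations), !is.null(names(annotations)))
  families <- sort(unique(unlist(lapply(annotations, function(a) a$family))))
  rows <- list()
  for (sp in names(annotations)) {
    a <- annotations[[sp]]
    if (!all(a$status %in% c("complete", "partial", "pseudogene")))
      stop("unknown status values for species ", sp)
    for (fam in families) {
      sub <- a[a$family == fam, ]
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, family = fam,
        complete = sum(sub$status == "complete"),
        partial = sum(sub$status == "partial"),
        pseudogene = sum(sub$status == "pseudogene"),
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("family_census", "data.frame"))
}

# functional presence: at least one complete or partial copy
.census_presence <- function(census, fam) {
  sub <- census[census$family == fam, ]
  stats::setNames(sub$complete + sub$partial > 0, sub$species)
}

.census_counts <- function(census, fam) {
  sub <- census[census$family == fam, ]
  stats::setNames(sub$complete + sub$partial, sub$species)
}

#' Dollo gain/loss inference for gene families on a species tree
#'
#' Presence/absence of each family (at least one intact or partial copy)
#' is mapped by Dollo parsimony: a single gain on the stem of the smallest
#' clade containing all present species, with losses on the stems of the
#' maximal present-free subclades inside it. Ancestral copy numbers are
#' reconstructed by minimizing the total absolute count change along the
#' tree (linear-cost Sankoff); a count increase of at least
#' `expansion_fold` between parent and child emits an expansion event, and
#' the converse a contraction.
#'
#' @param census a [family_census()].
#' @param tree rooted `ape::phylo` tree whose tips exactly match the
#'   census species. Internal nodes may carry labels; unlabeled internal
#'   branches are named `node<k>`, and the root stem is `"root"`.
#' @param expansion_fold fold change emitting expansion/contraction events
#'   (default 4).
#' @return data.frame of `gain_loss_event`s: `family`, `branch` (named by
#'   the child node of the branch), `type`
#'   (gain/loss/expansion/contraction), `magnitude` (count change).
#' @export
dollo_gain_loss <- function(census, tree, expansion_fold = 4) {
  stopifnot(inherits(tree, "phylo"))
  species <- unique(census$species)
  if (!setequal(tree$tip.label, species))
    stop("tree tips must match census species exactly")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  node_name <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    if (v == root) return("root")
    if (!is.null(tree$node.label) &&
        nzchar(tree$node.label[v - ntip])) tree$node.label[v - ntip]
    else paste0("node", v)
  }
  children <- split(tree$edge[, 2], tree$edge[, 1])
  po_edge <- ape::reorder.phylo(tree, "postorder")$edge
  postorder <- unique(po_edge[, 1]) # internal nodes, children first
  preorder <- rev(postorder)
  events <- list()
  add_event <- function(fam, branch, type, magnitude)
    events[[length(events) + 1L]] <<- data.frame(
      family = fam, branch = branch, type = type,
      magnitude = magnitude, stringsAsFactors = FALSE)

  for (fam in unique(census$family)) {
    pres <- .census_presence(census, fam)
    present_tips <- match(names(pres)[pres], tree$tip.label)
    if (length(present_tips) == 0L) next # absent everywhere: no events
    mrca <- if (length(present_tips) == 1L) present_tips
            else ape::getMRCA(tree, present_tips)
    # subtree presence state under Dollo: present at every node of the
    # MRCA clade except maximal subclades with no present descendants
    desc_present <- logical(ntip + nnode)
    desc_present[present_tips] <- TRUE
    for (v in postorder)
      desc_present[v] <- any(desc_present[children[[as.character(v)]]])
    in_clade <- logical(ntip + nnode)
    in_clade[mrca] <- TRUE
    for (v in preorder)
      for (ch in children[[as.character(v)]])
        if (in_clade[v]) in_clade[ch] <- TRUE
    state <- in_clade & desc_present
    add_event(fam, node_name(mrca), "gain", 1L)
    # losses: nodes in the clade whose parent is present but which have no
    # present descendants (maximal absent subclades)
    parent_of <- integer(ntip + nnode)
    parent_of[tree$edge[, 2]] <- tree$edge[, 1]
    for (v in seq_len(ntip + nnode)) {
      if (v == mrca || !in_clade[v]) next
      if (!state[v] && state[parent_of[v]])
        add_event(fam, node_name(v), "loss", -1L)
    }
    # ancestral counts by linear-cost Sankoff over the present clade
    counts <- .census_counts(census, fam)
    maxc <- max(counts)
    if (maxc > 0L) {
      anc <- .sankoff_counts(tree, counts, state, children, postorder,
                             preorder, ntip, nnode, mrca)
      for (v in seq_len(ntip + nnode)) {
        if (v == mrca || !in_clade[v] || !state[v]) next
        p <- parent_of[v]
        if (!state[p]) next
        a <- anc[p]; b <- anc[v]
        if (a >= 1 && b >= expansion_fold * a)
          add_event(fam, node_name(v), "expansion", b - a)
        else if (b >= 1 && a >= expansion_fold * b)
          add_event(fam, node_name(v), "contraction", b - a)
      }
    }
  }
  if (length(events) == 0L)
    return(data.frame(family = character(), branch = character(),
                      type = character(), magnitude = integer()))
  do.call(rbind, events)
}

# minimize total |parent - child| count change over nodes with state TRUE;
# classic linear-cost Sankoff via per-node piecewise-linear cost, here the
# small-state DP over 0..max(counts)
.sankoff_counts <- function(tree, counts, state, children, postorder,
                            preorder, ntip, nnode, mrca) {
  states <- 0:max(counts)
  ns <- length(states)
  cost <- matrix(Inf, ntip + nnode, ns)
  for (v in seq_len(ntip)) {
    if (!state[v]) next
    c0 <- counts[tree$tip.label[v]]
    cost[v, ] <- abs(states - c0)
  }
  for (v in postorder) {
    if (!state[v]) next
    kids <- children[[as.character(v)]]
    kids <- kids[state[kids]]
    if (length(kids) == 0L) next
    for (s in seq_len(ns)) {
      tot <- 0
      for (k in kids)
        tot <- tot + min(cost[k, ] + abs(states - states[s]))
      cost[v, s] <- tot
    }
  }
  anc <- rep(NA_integer_, ntip + nnode)
  for (v in seq_len(ntip)) if (state[v]) anc[v] <- counts[tree$tip.label[v]]
  # choose root state, then propagate down preferring minimal change
  anc[mrca] <- states[which.min(cost[mrca, ])]
  for (v in preorder) {
    if (is.na(anc[v])) next
    for (ch in children[[as.character(v)]]) {
      if (ch <= ntip || !state[ch]) next
      opts <- cost[ch, ] + abs(states - anc[v])
      anc[ch] <- states[which.min(opts)]
    }
  }
  anc
}

#' Build a comparative locus map across species
#'
#' Ordered per-species gene lists with orthology links between consecutive
#' species, cluster boxes for families with more than four members, and
#' discontinuity marks from the locus regions.
#'
#' @param annotations named list (per species) of data.frames with columns
#'   `gene`, `family`, `strand` in locus order.
#' @param ortholog_maps list of data.frames (`gene_a`, `gene_b`), one per
#'   consecutive species pair.
#' @param regions optional named list of [locus_region()]s, used for
#'   discontinuity (`~`) marks.
#' @param cluster_min family size above which a family is rendered as one
#'   cluster box (default 4, i.e. boxes for > 4 members).
#' @return object of class `locus_map`; its `print()` method renders the
#'   map as text.
#' @export
build_locus_map <- function(annotations, ortholog_maps = list(),
                            regions = NULL, cluster_min = 4L) {
  stopifnot(is.list(annotations), length(annotations) >= 2L)
  tracks <- list()
  for (sp in names(annotations)) {
    a <- annotations[[sp]]
    tokens <- list()
    i <- 1L
    while (i <= nrow(a)) {
      fam <- a$family[i]
      j <- i
      while (j < nrow(a) && a$family[j + 1L] == fam) j <- j + 1L
      run <- j - i + 1L
      if (run > cluster_min) {
        tokens[[length(tokens) + 1L]] <- list(kind = "box", family = fam,
                                              n = run,
                                              genes = a$gene[i:j])
      } else {
        for (k in i:j)
          tokens[[length(tokens) + 1L]] <- list(kind = "gene",
                                                gene = a$gene[k],
                                                family = a$family[k],
                                                strand = a$strand[k])
      }
      i <- j + 1L
    }
    disc <- if (!is.null(regions) && sp %in% names(regions))
      any(regions[[sp]]$discontinuity) else FALSE
    tracks[[sp]] <- list(tokens = tokens, discontinuity = disc)
  }
  structure(list(tracks = tracks, links = ortholog_maps,
                 cluster_min = cluster_min), class = "locus_map")
}

#' @export
print.locus_map <- function(x, ...) {
  for (sp in names(x$tracks)) {
    tr <- x$tracks[[sp]]
    toks <- vapply(tr$tokens, function(t) {
      if (t$kind == "box") sprintf("[%s#%d]", t$family, t$n)
      else if (identical(t$strand, "-")) paste0("<", t$gene)
      else paste0(t$gene, ">")
    }, character(1))
    cat(sprintf("%-12s %s%s\n", sp, paste(toks, collapse = " "),
                if (tr$discontinuity) " ~" else ""))
  }
  if (length(x$links)) {
    n <- vapply(x$links, nrow, integer(1))
    cat("orthology links between consecutive species:",
        paste(n, collapse = ", "), "\n")
  }
  invisible(x)
}
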