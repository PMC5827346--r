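# Shared fixtures and independent oracles. Loci are generated in code (no
# stored data) and cached per session so several test files can share one
# draw.

.fixture_cache <- new.env(parent = emptyenv())

cached_locus <- function(seed, ...) {
  key <- paste0("locus_", seed, "_", paste(deparse(list(...)), collapse = ""))
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  loc <- generate_edc_locus(synthetic_config(seed = seed, ...))
  .fixture_cache[[key]] <- loc
  loc
}

cached_region <- function(seed, ...) {
  key <- paste0("region_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  loc <- cached_locus(seed, ...)
  tr <- loc$truth
  markers <- list(protein_record("S100A12", tr$proteins[["S100A12"]]),
                  protein_record("S100A11", tr$proteins[["S100A11"]]))
  reg <- find_flanked_region(loc$scaffolds, markers)
  .fixture_cache[[key]] <- reg
  reg
}

rand_protein <- function(n, alphabet = c("A","R","N","D","C","Q","E","G",
                                         "H","I","L","K","M","F","P","S",
                                         "T","W","Y","V")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# exhaustive tandem-decomposition oracle for count_motif_copies: recursion
# over every way of chaining single-copy matches with bounded spacers; no
# dynamic programming, so it is independent of the production path
brute_repeat_copies <- function(protein, pattern, max_mismatch = 1L,
                                max_spacer = 2L) {
  pat <- parse_motif_pattern(pattern)
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  match_lens <- function(at) {
    # all (length) values of a single copy starting at `at`
    res <- integer(0)
    rec <- function(pos_idx, consumed, mm) {
      if (pos_idx > length(pat)) { res <<- c(res, consumed); return() }
      p <- pat[[pos_idx]]
      optional <- any(p == "")
      resid <- p[p != ""]
      if (optional) rec(pos_idx + 1L, consumed, mm)
      k <- at + consumed
      if (k <= n) {
        if (chars[k] %in% resid) rec(pos_idx + 1L, consumed + 1L, mm)
        else if (!optional && mm + 1L <= max_mismatch)
          rec(pos_idx + 1L, consumed + 1L, mm + 1L)
      }
    }
    rec(1L, 0L, 0L)
    unique(res[res > 0L])
  }
  best <- 0L
  chain <- function(at, copies) {
    if (copies > best) best <<- copies
    for (len in match_lens(at)) {
      for (sp in 0:max_spacer) {
        nxt <- at + len + sp
        if (nxt <= n) chain(nxt, copies + 1L)
        else if (copies + 1L > best) best <<- copies + 1L
      }
    }
  }
  for (i in seq_len(n)) if (length(match_lens(i))) chain(i, 0L)
  best
}

# exhaustive Dollo oracle: enumerate all internal presence assignments with
# at most one gain edge, minimize losses, return the gain node and the loss
# nodes (child ends of the respective edges)
dollo_oracle <- function(tree, presence) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  tips <- as.integer(presence[tree$tip.label])
  best <- NULL
  for (mask in 0:(2^nnode - 1L)) {
    states <- c(tips, as.integer(intToBits(mask)[seq_len(nnode)]))
    gains <- 0L; losses <- integer(0); gain_node <- NA_integer_
    if (states[root] == 1L) { gains <- gains + 1L; gain_node <- root }
    ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (states[p] == 0L && states[ch] == 1L) {
        gains <- gains + 1L; gain_node <- ch
      } else if (states[p] == 1L && states[ch] == 0L) {
        losses <- c(losses, ch)
      }
    }
    if (gains != 1L) ok <- FALSE
    if (ok && (is.null(best) || length(losses) < length(best$losses)))
      best <- list(gain = gain_node, losses = sort(losses))
  }
  best
}

# expected amino-acid identity of a codon after mutation under the
# generator's model: per-site substitution probability d with 2:1
# transition bias, proposals creating a stop reverted site by site
expected_codon_identity <- function(codon, d) {
  bases <- c("A", "C", "G", "T")
  ts <- c(A = "G", C = "T", G = "A", T = "C")
  stops <- c("TAA", "TAG", "TGA")
  code <- Biostrings::GENETIC_CODE
  dist <- stats::setNames(1, codon)
  for (site in 1:3) {
    nxt <- numeric(0)
    add <- function(cd, p) nxt[cd] <<- (if (is.na(nxt[cd])) 0 else nxt[cd]) + p
    for (cd in names(dist)) {
      p0 <- dist[[cd]]
      add(cd, p0 * (1 - d))
      for (b in bases) {
        old <- substr(cd, site, site)
        if (b == old) next
        pb <- if (b == ts[[old]]) d * 2 / 3 else d * 1 / 6
        new <- cd
        substr(new, site, site) <- b
        if (new %in% stops) add(cd, p0 * pb) else add(new, p0 * pb)
      }
    }
    dist <- nxt[!is.na(nxt)]
  }
  aa0 <- as.character(code[codon])
  sum(dist[as.character(code[names(dist)]) == aa0])
}
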