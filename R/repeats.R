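# Degenerate tandem-repeat detection in proteins. The motif grammar
# transcribes the field's notation directly: fixed residues, alternation
# sets in parentheses separated by "|", and "-" inside a set marking the
# position as optional, e.g. CCDPCQ(K|-)(T|P)(V|-) -- the avian EDCRP
# repeat unit. A copy may deviate from the pattern at up to `max_mismatch`
# non-optional positions, and consecutive copies may be separated by at
# most `max_spacer` residues.

#' Parse a repeat-motif pattern
#'
#' @param pattern pattern string, e.g. `"CCDPCQ(K|-)(T|P)(V|-)"`.
#' @return object of class `motif_pattern`: list of positions, each a
#'   character vector of allowed residues (`""` = position may be absent).
#' @export
parse_motif_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  chars <- strsplit(pattern, "")[[1]]
  pos <- list()
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "(") {
      j <- i
      while (j <= length(chars) && chars[j] != ")") j <- j + 1L
      if (j > length(chars)) stop("unbalanced parenthesis in pattern")
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      opts <- strsplit(body, "|", fixed = TRUE)[[1]]
      opts[opts == "-"] <- ""
      if (!all(opts %in% c(.AA20, "")))
        stop("invalid residues in pattern set: ", body)
      pos[[length(pos) + 1L]] <- opts
      i <- j + 1L
    } else {
      if (!chars[i] %in% .AA20)
        stop("invalid residue in pattern: ", chars[i])
      pos[[length(pos) + 1L]] <- chars[i]
      i <- i + 1L
    }
  }
  n_required <- sum(vapply(pos, function(p) !any(p == ""), logical(1)))
  if (n_required < 3L)
    stop("pattern must have at least 3 non-optional positions")
  structure(pos, class = "motif_pattern")
}

.as_pattern <- function(pattern) {
  if (inherits(pattern, "motif_pattern")) pattern
  else parse_motif_pattern(pattern)
}

# all ways one copy of the pattern can match starting at 1-based position
# `at`: data.frame of (len, mismatches), minimal mismatches per length
.copy_matches_at <- function(chars, at, pattern, max_mismatch) {
  n <- length(chars)
  # state: position index -> set of (consumed, mismatches)
  states <- list(c(consumed = 0L, mismatches = 0L))
  for (p in pattern) {
    nxt <- list()
    optional <- any(p == "")
    resid <- p[p != ""]
    for (st in states) {
      if (optional) nxt[[length(nxt) + 1L]] <- st # skip the position
      k <- at + st["consumed"]
      if (k <= n) {
        mm <- st["mismatches"] + as.integer(!(chars[k] %in% resid) && !optional)
        # an optional position, if present, must match one of its residues
        if (optional && !(chars[k] %in% resid)) {
          # treat as skipped only (already added); do not consume
        } else if (mm <= max_mismatch) {
          nxt[[length(nxt) + 1L]] <- c(consumed = st[["consumed"]] + 1L,
                                       mismatches = as.integer(mm))
        }
      }
    }
    if (length(nxt) == 0L) return(NULL)
    # keep minimal mismatches per consumed count
    key <- vapply(nxt, `[`, numeric(1), "consumed")
    states <- lapply(split(seq_along(nxt), key), function(ix) {
      nxt[[ix[which.min(vapply(nxt[ix], `[`, numeric(1), "mismatches"))]]]
    })
  }
  do.call(rbind, lapply(states, function(st)
    data.frame(len = st[["consumed"]], mismatches = st[["mismatches"]])))
}

#' Count tandem copies of a degenerate motif
#'
#' Finds the maximal tandem array of pattern copies by dynamic programming
#' over match positions, allowing up to `max_mismatch` deviations per copy
#' and spacers of up to `max_spacer` residues between consecutive copies.
#' Ties on copy count are broken toward the leftmost array start.
#'
#' @param protein protein string or [protein_record()].
#' @param pattern pattern string or [parse_motif_pattern()] object.
#' @param max_mismatch allowed deviations per copy (default 1).
#' @param max_spacer allowed residues between consecutive copies (default 2).
#' @return a `repeat_annotation` (list with `protein_id`, `pattern`,
#'   `copies`, `span` and a `per_copy` data.frame of intervals, matched
#'   strings and deviation counts), or `NULL` when the motif is absent.
#' @export
count_motif_copies <- function(protein, pattern, max_mismatch = 1L,
                               max_spacer = 2L) {
  seq <- .as_protein_string(protein)
  pid <- if (inherits(protein, "protein_record")) protein$id else NA_character_
  pat <- .as_pattern(pattern)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  # per start position: data.frame(len, mismatches) or NULL
  matches <- lapply(seq_len(n), function(i)
    .copy_matches_at(chars, i, pat, max_mismatch))
  # DP right to left: best chain starting with a copy at i
  copies_from <- integer(n + 1L)
  choice <- vector("list", n)
  for (i in rev(seq_len(n))) {
    best <- 0L; pick <- NULL
    m <- matches[[i]]
    if (!is.null(m)) {
      for (r in seq_len(nrow(m))) {
        len <- m$len[r]
        if (len == 0L) next
        nxt_best <- 0L; nxt_at <- NA_integer_
        for (sp in 0:max_spacer) {
          j <- i + len + sp
          if (j > n + 1L) break
          cf <- if (j <= n) copies_from[j] else 0L
          if (cf > nxt_best) { nxt_best <- cf; nxt_at <- j }
        }
        total <- 1L + nxt_best
        # ties on copy count prefer fewer deviations, then the longer
        # (more complete) copy
        better <- total > best ||
          (total == best && !is.null(pick) &&
             (m$mismatches[r] < pick$mismatches ||
                (m$mismatches[r] == pick$mismatches && len > pick$len)))
        if (better) {
          best <- total
          pick <- list(len = len, mismatches = m$mismatches[r],
                       nxt = if (nxt_best > 0L) nxt_at else NA_integer_)
        }
      }
    }
    copies_from[i] <- best
    choice[i] <- list(pick)
  }
  if (max(copies_from) == 0L) return(NULL)
  start <- which.max(copies_from) # leftmost maximal array
  per <- list()
  i <- start
  while (!is.na(i) && !is.null(choice[[i]])) {
    pc <- choice[[i]]
    per[[length(per) + 1L]] <- data.frame(
      start = i - 1L, end = i - 1L + pc$len,
      matched = paste0(chars[i:(i + pc$len - 1L)], collapse = ""),
      deviations = pc$mismatches)
    i <- pc$nxt
  }
  per <- do.call(rbind, per)
  structure(list(protein_id = pid,
                 pattern = paste0(vapply(pat, function(p)
                   if (length(p) == 1L && !any(p == "")) p
                   else paste0("(", paste0(ifelse(p == "", "-", p),
                                           collapse = "|"), ")"),
                   character(1)), collapse = ""),
                 copies = nrow(per),
                 span = c(per$start[1], per$end[nrow(per)]),
                 per_copy = per),
            class = "repeat_annotation")
}

#' @export
print.repeat_annotation <- function(x, ...) {
  cat(sprintf("<repeat_annotation> %s: %d copies of %s over [%d,%d)\n",
              x$protein_id, x$copies, x$pattern, x$span[1], x$span[2]))
  invisible(x)
}

#' Discover tandem repeats de novo
#'
#' Self-comparison at every candidate unit length: positions where the
#' residue equals the residue one unit downstream are tallied in sliding
#' windows; maximal windows with periodic identity at least
#' `min_period_identity` and at least `min_copies` copies are reported with
#' a majority-rule unit consensus. Overlapping candidate arrays are
#' resolved by maximal copy count, then smallest unit, then leftmost start.
#'
#' @param protein protein string or [protein_record()].
#' @param min_unit,max_unit unit length bounds (residues).
#' @param min_copies minimum copy count (default 3).
#' @param min_period_identity minimum fraction of positions identical to
#'   the position one unit downstream (default 0.7).
#' @return list of `repeat_annotation` objects (possibly empty), each with
#'   a `unit` consensus field.
#' @export
discover_tandem_repeats <- function(protein, min_unit = 3L, max_unit = 15L,
                                    min_copies = 3L,
                                    min_period_identity = 0.7) {
  seq <- .as_protein_string(protein)
  pid <- if (inherits(protein, "protein_record")) protein$id else NA_character_
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (min_unit < 2L) stop("min_unit must be at least 2")
  cands <- list()
  for (u in seq.int(min_unit, min(max_unit, n %/% min_copies))) {
    eq <- chars[seq_len(n - u)] == chars[seq_len(n - u) + u]
    # simple segmentation: grow maximal segments of eq with identity >= cutoff
    i <- 1L
    while (i <= length(eq)) {
      if (!eq[i]) { i <- i + 1L; next }
      j <- i
      best_j <- i
      mism <- 0L
      while (j <= length(eq)) {
        if (!eq[j]) mism <- mism + 1L
        if (mean(eq[i:j]) >= min_period_identity) best_j <- j
        if (mism > u) break # too degenerate to continue
        j <- j + 1L
      }
      span_len <- best_j - i + 1L + u
      copies <- span_len %/% u
      if (copies >= min_copies) {
        start0 <- i - 1L
        # trim edge copies that deviate too much from the consensus (the
        # periodicity run can leak into flanking sequence by chance)
        repeat {
          block <- matrix(chars[(start0 + 1L):(start0 + copies * u)],
                          nrow = u)
          consensus <- apply(block, 1, function(col)
            names(sort(table(col), decreasing = TRUE))[1])
          dev <- colSums(block != consensus)
          max_dev <- (1 - min_period_identity) * u
          if (copies > min_copies && dev[copies] > max_dev) {
            copies <- copies - 1L
          } else if (copies > min_copies && dev[1] > max_dev) {
            start0 <- start0 + u; copies <- copies - 1L
          } else break
        }
        if (copies >= min_copies)
          cands[[length(cands) + 1L]] <- list(
            unit_len = u, copies = copies,
            span = c(start0, start0 + copies * u),
            unit = paste0(consensus, collapse = ""))
      }
      i <- best_j + u
    }
  }
  if (length(cands) == 0L) return(list())
  ord <- order(-vapply(cands, `[[`, integer(1), "copies"),
               vapply(cands, `[[`, integer(1), "unit_len"),
               vapply(cands, function(c) c$span[1], numeric(1)))
  cands <- cands[ord]
  out <- list()
  for (cd in cands) {
    clash <- FALSE
    for (o in out)
      if (.intervals_overlap(o$span, cd$span)) { clash <- TRUE; break }
    if (clash) next
    per <- data.frame(
      start = cd$span[1] + cd$unit_len * (seq_len(cd$copies) - 1L),
      end = cd$span[1] + cd$unit_len * seq_len(cd$copies))
    per$matched <- vapply(seq_len(cd$copies), function(k)
      paste0(chars[(per$start[k] + 1L):per$end[k]], collapse = ""),
      character(1))
    per$deviations <- vapply(per$matched, function(m)
      sum(strsplit(m, "")[[1]] != strsplit(cd$unit, "")[[1]]), integer(1),
      USE.NAMES = FALSE)
    out[[length(out) + 1L]] <- structure(
      list(protein_id = pid, pattern = cd$unit, unit = cd$unit,
           copies = cd$copies, span = cd$span, per_copy = per),
      class = "repeat_annotation")
  }
  out
}

#' Compare the repeat architecture of two orthologous proteins
#'
#' Counts pattern copies in each protein, aligns the regions outside the
#' detected repeat spans globally, and reports the signed copy-number
#' expansion of the second protein relative to the first -- the comparison
#' behind the model of avian EDCRP arising by internal repeat expansion of
#' a crocodilian-like ancestor.
#'
#' @param protein_a,protein_b protein strings or [protein_record()]s.
#' @param pattern repeat pattern (string or [parse_motif_pattern()]).
#' @param scheme a [default_score_scheme()].
#' @param ... passed to [count_motif_copies()].
#' @return list with `terminal_identity` (percent over the aligned terminal
#'   domains), `copies_a`, `copies_b`, `expansion` (`copies_b - copies_a`).
#' @export
compare_ortholog_architecture <- function(protein_a, protein_b, pattern,
                                          scheme = default_score_scheme(),
                                          ...) {
  sa <- .as_protein_string(protein_a); sb <- .as_protein_string(protein_b)
  if (nchar(sa) == 0L || nchar(sb) == 0L) stop("empty protein")
  ra <- count_motif_copies(sa, pattern, ...)
  rb <- count_motif_copies(sb, pattern, ...)
  split_termini <- function(seq, rep_ann) {
    n <- nchar(seq)
    if (is.null(rep_ann)) {
      h <- n %/% 2L
      list(nt = substr(seq, 1, h), ct = substr(seq, h + 1L, n))
    } else {
      list(nt = substr(seq, 1, rep_ann$span[1]),
           ct = substr(seq, rep_ann$span[2] + 1L, n))
    }
  }
  ta <- split_termini(sa, ra); tb <- split_termini(sb, rb)
  idents <- c()
  if (nchar(ta$nt) && nchar(tb$nt))
    idents <- c(idents, global_align(ta$nt, tb$nt, scheme)$identity)
  if (nchar(ta$ct) && nchar(tb$ct))
    idents <- c(idents, global_align(ta$ct, tb$ct, scheme)$identity)
  ca <- if (is.null(ra)) 0L else ra$copies
  cb <- if (is.null(rb)) 0L else rb$copies
  list(terminal_identity = if (length(idents)) 100 * mean(idents) else NA_real_,
       copies_a = ca, copies_b = cb, expansion = cb - ca)
}
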