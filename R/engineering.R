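#' Variant libraries
#'
#' A `variant_library` couples a reference sequence with either a
#' materialized data.frame of variants (saturation and single X-to-R
#' libraries) or a streaming enumerator (combinatorial X-to-R libraries,
#' which are never held in memory at once).
#'
#' @name variant_library
NULL

.new_library <- function(reference, variants = NULL, spec = list(),
                         positions = NULL) {
  structure(list(reference = reference, variants = variants, spec = spec,
                 positions = positions),
            class = "variant_library")
}

#' @export
print.variant_library <- function(x, ...) {
  n <- library_size(x)
  cat(sprintf("<variant_library> kind=%s, %s variants%s\n",
              x$spec$kind, format(n, big.mark = ","),
              if (is.null(x$variants)) " (streaming)" else ""))
  invisible(x)
}

#' Number of variants in a library
#' @param lib A `variant_library`.
#' @export
library_size <- function(lib) {
  if (!is.null(lib$variants)) return(nrow(lib$variants))
  m <- length(lib$positions)
  if (lib$spec$k > m) 0 else choose(m, lib$spec$k)
}

#' Saturation mutagenesis library
#'
#' All 19 substitutions at every non-excluded position:
#' `(L - |excluded|) * 19` variants. A 408-residue reference yields 7752, a
#' 167-residue one 3173, and excluding two positions of the latter 3135.
#'
#' @param reference A `protein_record`.
#' @param excluded_positions Integer set of 1-based positions left
#'   untouched.
#' @return A materialized `variant_library`.
#' @export
enumerate_saturation <- function(reference, excluded_positions = integer(0)) {
  stopifnot(inherits(reference, "protein_record"))
  L <- reference$L
  excluded_positions <- as.integer(excluded_positions)
  if (any(excluded_positions < 1L | excluded_positions > L))
    stop("excluded position out of range 1..", L)
  ref <- strsplit(reference$sequence, "")[[1]]
  pos <- setdiff(seq_len(L), excluded_positions)
  rows <- lapply(pos, function(p) {
    mt <- setdiff(AA_LETTERS, ref[p])
    data.frame(variant = sprintf("%s%d%s", ref[p], p, mt),
               position = p, wt = ref[p], mt = mt,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  .new_library(reference, df,
               spec = list(kind = "saturation", k = 1L,
                           excluded_positions = excluded_positions))
}

#' Single X-to-R library
#'
#' One arginine substitution per non-arginine position.
#'
#' @param reference A `protein_record`.
#' @export
enumerate_xr_single <- function(reference) {
  stopifnot(inherits(reference, "protein_record"))
  ref <- strsplit(reference$sequence, "")[[1]]
  pos <- which(ref != "R")
  df <- if (length(pos) == 0L) {
    data.frame(variant = character(0), position = integer(0),
               wt = character(0), mt = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(variant = sprintf("%s%dR", ref[pos], pos),
               position = pos, wt = ref[pos], mt = "R",
               stringsAsFactors = FALSE)
  }
  .new_library(reference, df, spec = list(kind = "xr_single", k = 1L,
                                          excluded_positions = integer(0)))
}

#' Combinatorial X-to-R library (streaming)
#'
#' All `choose(m, k)` variants substituting arginine at every k-subset of
#' the m non-arginine positions. The library is enumerated through a chunk
#' stream (all combinations sharing a prefix of k-1 positions, with the
#' last position vectorized), so the 8,510,740-variant triple library over
#' 372 positions is counted and scored in bounded memory.
#'
#' @param reference A `protein_record`.
#' @param k Number of simultaneous substitutions (>= 1).
#' @return A streaming `variant_library`.
#' @export
enumerate_xr_combinatorial <- function(reference, k) {
  stopifnot(inherits(reference, "protein_record"), k >= 1)
  ref <- strsplit(reference$sequence, "")[[1]]
  pos <- which(ref != "R")
  if (k > length(pos))
    warning("k = ", k, " exceeds the ", length(pos),
            " non-arginine positions; library is empty")
  .new_library(reference, variants = NULL,
               spec = list(kind = "xr_combinatorial", k = as.integer(k),
                           excluded_positions = integer(0)),
               positions = pos)
}

# chunk iterator over k-combinations of seq_len(m): each call returns
# list(prefix = indices of the first k-1 elements, lasts = vector of last
# elements), or NULL when exhausted.
.combo_stream <- function(m, k) {
  if (k > m || m < 1L) return(function() NULL)
  if (k == 1L) {
    done <- FALSE
    return(function() {
      if (done) return(NULL)
      done <<- TRUE
      list(prefix = integer(0), lasts = seq_len(m))
    })
  }
  prefix <- seq_len(k - 1L)
  finished <- FALSE
  function() {
    repeat {
      if (finished) return(NULL)
      out <- if (prefix[k - 1L] < m)
        list(prefix = prefix, lasts = (prefix[k - 1L] + 1L):m) else NULL
      # advance prefix (combination successor; prefixes whose last element
      # reaches m produce no lasts and are skipped)
      i <- k - 1L
      while (i >= 1L && prefix[i] == m - (k - 1L - i)) i <- i - 1L
      if (i < 1L) finished <<- TRUE
      else {
        prefix[i] <<- prefix[i] + 1L
        if (i < k - 1L)
          prefix[(i + 1L):(k - 1L)] <<- prefix[i] + seq_len(k - 1L - i)
      }
      if (!is.null(out)) return(out)
    }
  }
}

#' Count a streaming library by full enumeration
#'
#' Iterates the chunk stream and sums chunk sizes; equals
#' [library_size()]'s closed form but is an actual streamed count.
#'
#' @param lib A streaming `variant_library`.
#' @export
stream_count <- function(lib) {
  if (!is.null(lib$variants)) return(nrow(lib$variants))
  nxt <- .combo_stream(length(lib$positions), lib$spec$k)
  total <- 0
  repeat {
    ch <- nxt()
    if (is.null(ch)) break
    total <- total + length(ch$lasts)
  }
  total
}

# variant string for a set of X->R position indices (into lib$positions)
.xr_variant_string <- function(lib, idx) {
  ref <- strsplit(lib$reference$sequence, "")[[1]]
  p <- lib$positions[idx]
  paste(sprintf("%s%dR", ref[p], p), collapse = "/")
}

#' Remove variants containing banned substitutions
#'
#' Drops every variant that contains at least one of the banned single
#' substitutions (given as strings like `"Y388R"`). For streaming X-to-R
#' libraries this removes the banned positions from the enumeration; for
#' materialized libraries it filters rows.
#'
#' @param lib A `variant_library`.
#' @param banned Character vector of single-substitution strings.
#' @return A filtered `variant_library`.
#' @export
filter_by_constituents <- function(lib, banned) {
  if (length(banned) == 0L) return(lib)
  bv <- lapply(banned, parse_variant)
  if (any(vapply(bv, nrow, 1L) != 1L))
    stop("banned entries must be single substitutions")
  bdf <- do.call(rbind, bv)
  ref <- strsplit(lib$reference$sequence, "")[[1]]
  bad <- which(ref[bdf$position] != bdf$wt)
  if (length(bad) > 0L)
    stop("banned substitution '", banned[bad[1]],
         "' disagrees with the reference (position ", bdf$position[bad[1]],
         " is '", ref[bdf$position[bad[1]]], "')")
  if (is.null(lib$variants)) {
    if (any(bdf$mt != "R"))
      stop("streaming X-to-R libraries can only ban X-to-R substitutions")
    out <- lib
    out$positions <- setdiff(lib$positions, bdf$position)
    return(out)
  }
  bstr <- sprintf("%s%d%s", bdf$wt, bdf$position, bdf$mt)
  keep <- vapply(strsplit(lib$variants$variant, "/", fixed = TRUE),
                 function(parts) !any(parts %in% bstr), TRUE)
  out <- lib
  out$variants <- lib$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  out
}

#' Top and bottom blocks of a score table
#'
#' Returns the `n_top` highest-scoring and `n_bottom` lowest-scoring
#' variants; ties are broken by variant-string lexicographic order, and the
#' two blocks are guaranteed disjoint.
#'
#' @param scores A `score_table`.
#' @param n_top,n_bottom Block sizes; their sum must not exceed the table.
#' @return List with data.frames `top` (descending score) and `bottom`
#'   (ascending score).
#' @export
select_extremes <- function(scores, n_top, n_bottom) {
  n <- nrow(scores)
  if (n_top + n_bottom > n)
    stop("n_top + n_bottom = ", n_top + n_bottom, " exceeds table size ", n)
  ord <- order(-scores$score, scores$variant)
  top <- scores[ord[seq_len(n_top)], , drop = FALSE]
  bottom <- scores[rev(ord)[seq_len(n_bottom)], , drop = FALSE]
  bottom <- bottom[order(bottom$score, bottom$variant), , drop = FALSE]
  rownames(top) <- rownames(bottom) <- NULL
  list(top = top, bottom = bottom)
}

#' Score a streaming X-to-R library and keep the extremes
#'
#' Streams the combinatorial enumeration, scoring each chunk from the
#' precomputed per-position X-to-R gains (scores are additive over
#' constituents), and maintains bounded top/bottom buffers, so the
#' 8,510,740-variant triple library is ranked without materializing it.
#'
#' @param table A `logit_table` of the reference.
#' @param lib A streaming `variant_library` from
#'   [enumerate_xr_combinatorial()] (possibly filtered).
#' @param n_top,n_bottom Number of extreme variants to keep.
#' @return List with `top`, `bottom` score tables and `n_scored`.
#' @export
stream_select_extremes <- function(table, lib, n_top = 10, n_bottom = 10) {
  stopifnot(inherits(lib, "variant_library"), is.null(lib$variants))
  ref <- strsplit(attr(table, "reference"), "")[[1]]
  ids <- .token_ids()
  pos <- lib$positions
  g <- table[cbind(pos, unname(ids[rep("R", length(pos))]))] -
    table[cbind(pos, unname(ids[ref[pos]]))]
  k <- lib$spec$k
  m <- length(pos)
  nxt <- .combo_stream(m, k)
  cap <- function(buf, n_keep, decreasing) {
    ord <- order(buf$score, decreasing = decreasing)
    keep <- ord[seq_len(min(n_keep, length(buf$score)))]
    list(score = buf$score[keep],
         combos = buf$combos[keep, , drop = FALSE])
  }
  top <- list(score = numeric(0), combos = matrix(0L, 0, k))
  bot <- list(score = numeric(0), combos = matrix(0L, 0, k))
  n_scored <- 0
  prune_at <- 4L * max(n_top, n_bottom) + 64L
  repeat {
    ch <- nxt()
    if (is.null(ch)) break
    s <- sum(g[ch$prefix]) + g[ch$lasts]
    n_scored <- n_scored + length(s)
    thr_t <- if (length(top$score) >= n_top)
      min(sort(top$score, decreasing = TRUE)[seq_len(n_top)]) else -Inf
    sel <- which(s > thr_t | length(top$score) < n_top)
    if (length(sel) > 0L) {
      top$score <- c(top$score, s[sel])
      top$combos <- rbind(top$combos,
                          cbind(matrix(ch$prefix, length(sel), k - 1L,
                                       byrow = TRUE),
                                ch$lasts[sel]))
      if (length(top$score) > prune_at) top <- cap(top, n_top + 16L, TRUE)
    }
    thr_b <- if (length(bot$score) >= n_bottom)
      max(sort(bot$score)[seq_len(n_bottom)]) else Inf
    selb <- which(s < thr_b | length(bot$score) < n_bottom)
    if (length(selb) > 0L) {
      bot$score <- c(bot$score, s[selb])
      bot$combos <- rbind(bot$combos,
                          cbind(matrix(ch$prefix, length(selb), k - 1L,
                                       byrow = TRUE),
                                ch$lasts[selb]))
      if (length(bot$score) > prune_at) bot <- cap(bot, n_bottom + 16L, FALSE)
    }
  }
  finish <- function(buf, n_keep, decreasing) {
    if (length(buf$score) == 0L)
      return(data.frame(variant = character(0), score = numeric(0),
                        rank = integer(0)))
    vs <- vapply(seq_along(buf$score),
                 function(i) .xr_variant_string(lib, buf$combos[i, ]), "")
    ord <- if (decreasing) order(-buf$score, vs) else order(buf$score, vs)
    ord <- ord[seq_len(min(n_keep, length(ord)))]
    data.frame(variant = vs[ord], score = buf$score[ord],
               rank = seq_along(ord), stringsAsFactors = FALSE)
  }
  list(top = finish(top, n_top, TRUE), bottom = finish(bot, n_bottom, FALSE),
       n_scored = n_scored)
}

#' Compose multi-site candidates from beneficial singles
#'
#' For each requested size, greedily stacks the highest-scoring compatible
#' single substitutions (distinct positions, none banned) into one
#' multi-site variant, then ranks all composed candidates by their summed
#' score (scores are additive over constituents).
#'
#' @param singles A `score_table` of single variants (variant strings like
#'   `"E134S"`).
#' @param sizes Integer vector of requested mutation counts.
#' @param banned Optional character vector of banned single substitutions.
#' @return A `score_table` of composed variants with a `size` column,
#'   ranked by descending score.
#' @export
compose_from_beneficial <- function(singles, sizes, banned = character(0)) {
  stopifnot(nrow(singles) >= 1L, all(sizes >= 1))
  keep <- !(singles$variant %in% banned)
  singles <- singles[keep, , drop = FALSE]
  pos <- vapply(singles$variant, function(s) parse_variant(s)$position[1], 1L)
  ord <- order(-singles$score, singles$variant)
  out <- lapply(sizes, function(sz) {
    chosen <- integer(0)
    used_pos <- integer(0)
    for (i in ord) {
      if (pos[i] %in% used_pos) next
      chosen <- c(chosen, i)
      used_pos <- c(used_pos, pos[i])
      if (length(chosen) == sz) break
    }
    if (length(chosen) < sz)
      stop("size ", sz, " exceeds the available distinct positions (",
           length(unique(pos)), ")")
    chosen <- chosen[order(pos[chosen])]
    data.frame(variant = paste(singles$variant[chosen], collapse = "/"),
               score = sum(singles$score[chosen]), size = sz,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  ordr <- order(-res$score, res$variant)
  res <- res[ordr, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("score_table", class(res))
  res
}

#' Materialize a streaming library (small libraries only)
#'
#' Enumerates every variant of a streaming library into a data.frame; used
#' for oracle checks on small position sets.
#'
#' @param lib A streaming `variant_library`.
#' @param max_size Guard against accidental huge materializations.
#' @export
materialize_library <- function(lib, max_size = 1e6) {
  if (!is.null(lib$variants)) return(lib)
  if (library_size(lib) > max_size)
    stop("library too large to materialize (", library_size(lib), ")")
  nxt <- .combo_stream(length(lib$positions), lib$spec$k)
  rows <- list()
  i <- 0L
  repeat {
    ch <- nxt()
    if (is.null(ch)) break
    for (l in ch$lasts) {
      i <- i + 1L
      rows[[i]] <- .xr_variant_string(lib, c(ch$prefix, l))
    }
  }
  out <- lib
  out$variants <- data.frame(variant = unlist(rows) %||% character(0),
                             stringsAsFactors = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
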