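#' Encode a Raman spectrum as a spectral character sequence
#'
#' The Raman-shift axis is split into equal bins (default 100 cm^-1 wide, from
#' 0 to 1800 cm^-1, giving at most 18 bins) and every retained point
#' contributes the letter of its bin: bin 0 is "a", bin 17 is "r". Bins are
#' half-open `[lo, lo + width)` except the last, which is closed at the upper
#' range limit. Points outside the range are discarded with a warning; points
#' at or below the intensity threshold are dropped silently.
#'
#' By default points enter the sequence in order of decreasing intensity (ties
#' broken by ascending shift), so the sequence — and hence the star graph —
#' reflects the shape of the spectrum, not just its support. `ordering =
#' "shift_asc"` instead orders by ascending shift. `top_n` retains only the
#' `n` most intense points before ordering. `axis = "intensity"` is an
#' alternative mode that bins the intensity axis (18 equal bins from 0 to the
#' maximum intensity) instead of the shift axis.
#'
#' @param spectrum a [raman_spectrum()].
#' @param bin_width bin width in cm^-1 (default 100).
#' @param range numeric length-2, binned range in cm^-1 (default `c(0, 1800)`).
#'   The number of bins must not exceed 18 (letters "a" to "r").
#' @param ordering `"intensity_desc"` (default) or `"shift_asc"`.
#' @param threshold intensity cutoff; only points with intensity strictly
#'   above it are retained (default 0).
#' @param top_n optional: keep only the `top_n` most intense retained points.
#' @param axis `"shift"` (default) or `"intensity"` (alternative binning mode).
#' @return An object of class `spectral_sequence`: list with `symbols`
#'   (character vector over "a".."r"), and the encoding parameters.
#' @examples
#' sp <- raman_spectrum(c(1350, 1400, 1580), c(60, 30, 100))
#' encode_sequence(sp)$symbols  # "p" "n" "o"
#' @export
encode_sequence <- function(spectrum, bin_width = 100, range = c(0, 1800),
                            ordering = c("intensity_desc", "shift_asc"),
                            threshold = 0, top_n = NULL,
                            axis = c("shift", "intensity")) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  ordering <- match.arg(ordering)
  axis <- match.arg(axis)
  lo <- range[1L]; hi <- range[2L]
  if (!(bin_width > 0) || !(hi > lo)) stop("invalid binning range")
  n_bins <- ceiling((hi - lo) / bin_width)
  if (n_bins > 18L) {
    stop("binning would need ", n_bins, " bins; the alphabet caps at 18 (letters a-r)")
  }
  shift <- spectrum$shifts
  intensity <- spectrum$intensities
  in_range <- shift >= lo & shift <= hi
  if (any(!in_range)) {
    warning(sum(!in_range), " point(s) outside [", lo, ", ", hi, "] discarded")
  }
  keep <- in_range & intensity > threshold
  if (!any(keep)) stop("empty spectral sequence (no point above threshold inside the range)")
  shift <- shift[keep]
  intensity <- intensity[keep]
  if (!is.null(top_n)) {
    sel <- order(-intensity, shift)[seq_len(min(top_n, length(shift)))]
    sel <- sort(sel)
    shift <- shift[sel]
    intensity <- intensity[sel]
  }
  ord <- switch(ordering,
    intensity_desc = order(-intensity, shift),
    shift_asc = order(shift)
  )
  shift <- shift[ord]
  intensity <- intensity[ord]
  idx <- switch(axis,
    shift = {
      i <- floor((shift - lo) / bin_width)
      # closed last bin: the upper range limit itself falls in bin n_bins - 1
      pmin(i, n_bins - 1L)
    },
    intensity = {
      w <- max(intensity) / 18
      pmin(floor(intensity / w), 17L)
    }
  )
  structure(
    list(symbols = letters[idx + 1L], bin_width = bin_width, range = range,
         ordering = ordering, threshold = threshold, axis = axis),
    class = "spectral_sequence"
  )
}

#' @export
print.spectral_sequence <- function(x, ...) {
  cat(sprintf("Spectral sequence (%d symbols, %d branches): %s\n",
              length(x$symbols), length(unique(x$symbols)),
              paste(x$symbols, collapse = "")))
  invisible(x)
}

.as_symbols <- function(seq) {
  if (inherits(seq, "spectral_sequence")) return(seq$symbols)
  if (is.character(seq) && length(seq) == 1L) return(strsplit(seq, "")[[1L]])
  if (is.character(seq)) return(seq)
  stop("expected a spectral_sequence or a character vector")
}

#' Build the star graph of a spectral sequence
#'
#' Node 0 is the central node; sequence position i (1-based) becomes node i.
#' Each character type defines one branch, a path rooted at the center: the
#' first occurrence of a character links to the center, every later
#' occurrence links to the previous node of the same character. This yields
#' the plain adjacency matrix A (always a tree). The embedded edge set
#' additionally connects consecutive sequence positions (i, i+1) —
#' "recurrence information embedded" — giving the enriched matrix A_e.
#'
#' @param seq a `spectral_sequence`, a character vector of symbols, or a
#'   single string like `"abca"`.
#' @return Object of class `star_graph`: `n_nodes`, `labels` (symbol per
#'   position), `edges_plain` and `edges_embedded` (two-column matrices of
#'   node indices, center = 0).
#' @examples
#' g <- build_star_graph("ab")
#' g$edges_plain      # (0,1), (0,2)
#' g$edges_embedded   # adds the backbone edge (1,2)
#' @export
build_star_graph <- function(seq) {
  syms <- .as_symbols(seq)
  if (length(syms) < 1L) stop("empty sequence")
  if (!all(syms %in% letters[1:18])) {
    stop("symbol(s) outside the alphabet a-r: ",
         paste(unique(syms[!syms %in% letters[1:18]]), collapse = ", "))
  }
  n <- length(syms)
  last <- integer(0)
  from <- integer(n)
  for (i in seq_len(n)) {
    s <- syms[i]
    from[i] <- if (is.na(last[s][1L])) 0L else last[[s]]
    last[s] <- i
  }
  edges_plain <- cbind(from = from, to = seq_len(n))
  backbone <- if (n > 1L) cbind(from = seq_len(n - 1L), to = seq(2L, n)) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("from", "to")))
  emb <- rbind(edges_plain, backbone)
  emb <- cbind(from = pmin(emb[, 1L], emb[, 2L]), to = pmax(emb[, 1L], emb[, 2L]))
  emb <- emb[!duplicated(emb), , drop = FALSE]
  structure(
    list(n_nodes = n + 1L, labels = syms,
         edges_plain = edges_plain, edges_embedded = emb),
    class = "star_graph"
  )
}

#' @export
print.star_graph <- function(x, ...) {
  cat(sprintf("Star graph: %d nodes (center + %d), %d plain / %d embedded edges, branches: %s\n",
              x$n_nodes, x$n_nodes - 1L, nrow(x$edges_plain), nrow(x$edges_embedded),
              paste(sort(unique(x$labels)), collapse = "")))
  invisible(x)
}

#' Sparse adjacency matrix of a star graph
#'
#' @param graph a `star_graph`.
#' @param embedded if `TRUE`, return the recurrence-embedded matrix A_e.
#' @return A symmetric sparse 0/1 matrix of dimension `n_nodes` (node 0 in
#'   row/column 1).
#' @export
adjacency_matrix <- function(graph, embedded = FALSE) {
  stopifnot(inherits(graph, "star_graph"))
  e <- if (embedded) graph$edges_embedded else graph$edges_plain
  n <- graph$n_nodes
  Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]) + 1L,
                       j = c(e[, 2L], e[, 1L]) + 1L,
                       x = 1, dims = c(n, n))
}

.trace_powers <- function(A, k_max) {
  n <- nrow(A)
  out <- numeric(k_max + 1L)
  out[1L] <- n                 # Tr_0 = trace of the identity = matrix dimension
  if (k_max >= 1L) {
    P <- A
    out[2L] <- sum(Matrix::diag(P))
    for (k in seq_len(k_max - 1L) + 1L) {
      P <- P %*% A
      out[k + 1L] <- sum(Matrix::diag(P))
    }
  }
  stopifnot(max(abs(out - round(out))) < 1e-6)  # closed-walk counts are integers
  round(out)
}

#' Trace invariants (spectral moments) of a star graph
#'
#' Tr_k is the trace of the k-th power of the plain adjacency matrix A, i.e.
#' the number of closed walks of length k; Tre_k the same for the
#' recurrence-embedded matrix A_e. Computed by repeated matrix multiplication
#' (the entries are integer walk counts, far below the exact-integer range of
#' doubles).
#'
#' @param graph a `star_graph`.
#' @param k_max largest power (default 5, giving Tr_0..Tr_5).
#' @return Object of class `trace_invariants`: named vectors `tr` and `tre`.
#' @examples
#' trace_invariants(build_star_graph("ab"))$tr   # 3 0 4 0 8 0
#' trace_invariants(build_star_graph("ab"))$tre  # 3 0 6 6 18 30
#' @export
trace_invariants <- function(graph, k_max = 5L) {
  stopifnot(inherits(graph, "star_graph"), k_max >= 0L)
  ks <- paste0(seq(0L, k_max))
  tr <- stats::setNames(.trace_powers(adjacency_matrix(graph, FALSE), k_max), paste0("Tr", ks))
  tre <- stats::setNames(.trace_powers(adjacency_matrix(graph, TRUE), k_max), paste0("Tre", ks))
  structure(list(tr = tr, tre = tre, k_max = as.integer(k_max), n_nodes = graph$n_nodes),
            class = "trace_invariants")
}

#' @export
print.trace_invariants <- function(x, ...) {
  cat("Trace invariants (spectral moments):\n")
  print(rbind(Tr = x$tr, Tre = stats::setNames(x$tre, names(x$tr))))
  invisible(x)
}

#' @export
as.data.frame.trace_invariants <- function(x, ...) {
  as.data.frame(c(as.list(x$tr), as.list(x$tre)))
}

#' Collect trace invariants into a table keyed by identifier
#'
#' @param invariants named list of `trace_invariants` (names = CNT ids).
#' @return data.frame with a `cnt_id` column followed by Tr0..Tr_k and
#'   Tre0..Tre_k columns.
#' @export
invariant_table <- function(invariants) {
  stopifnot(is.list(invariants), !is.null(names(invariants)))
  rows <- lapply(invariants, as.data.frame)
  out <- do.call(rbind, rows)
  cbind(cnt_id = names(invariants), out, row.names = NULL)
}

#' Full star-graph transform of a Raman spectrum
#'
#' Composition of [encode_sequence()], [build_star_graph()] and
#' [trace_invariants()]: deterministic for fixed parameters.
#'
#' @param spectrum a [raman_spectrum()].
#' @param k_max largest matrix power (default 5).
#' @param ... encoding parameters passed to [encode_sequence()].
#' @return A `trace_invariants` object.
#' @examples
#' transform_spectrum(raman_spectrum(1350, 10))$tr  # 2 0 2 0 2 0
#' @export
transform_spectrum <- function(spectrum, k_max = 5L, ...) {
  trace_invariants(build_star_graph(encode_sequence(spectrum, ...)), k_max = k_max)
}
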