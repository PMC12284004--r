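# Pairwise global alignment with affine gaps (Gotoh), used by the
# center-star segment aligner. Short peptide loops only, so a plain R DP is
# ample. A gap of length L costs open + L * ext (the convention of
# Biostrings::pairwiseAlignment, which the tests use as an independent
# oracle).

.matrix_cache <- new.env(parent = emptyenv())

#' Retrieve a substitution matrix by name
#'
#' Loads a standard protein substitution matrix (from Biostrings) and caches
#' it. Currently BLOSUM45/50/62/80/100 and PAM30/40/70/120/250 are accepted.
#'
#' @param name Matrix name, e.g. `"BLOSUM62"`.
#' @return A numeric substitution matrix with residue row/column names.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  allowed <- c(paste0("BLOSUM", c(45, 50, 62, 80, 100)),
               paste0("PAM", c(30, 40, 70, 120, 250)))
  if (!name %in% allowed) {
    abort(sprintf("Unknown substitution matrix \"%s\".", name))
  }
  if (is.null(.matrix_cache[[name]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .matrix_cache[[name]] <- e[[name]]
  }
  .matrix_cache[[name]]
}

#' Alignment parameters
#'
#' @param matrix Substitution matrix name (default BLOSUM62).
#' @param gap_open Gap opening penalty (>= 0); a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param gap_extend Gap extension penalty per gap position (>= 0).
#' @param mode Segment alignment mode: `"center_star"` aligns interior loop
#'   segments with the center-star method; `"pad"` only justifies and pads
#'   them (a trivially verifiable baseline).
#' @return An object of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1,
                         mode = c("center_star", "pad")) {
  mode <- match.arg(mode)
  if (gap_open < 0 || gap_extend < 0) {
    abort("Gap penalties must be >= 0.")
  }
  structure(
    list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
         mode = mode),
    class = "align_params"
  )
}

#' @export
print.align_params <- function(x, ...) {
  cat(sprintf("<align_params> %s, gap open %g / extend %g, mode %s\n",
              x$matrix, x$gap_open, x$gap_extend, x$mode))
  invisible(x)
}

# Global pairwise alignment of two strings. Returns list(score, a, b) with
# `a`, `b` gapped to equal width. Deterministic traceback: on score ties the
# diagonal (match) state is preferred, then gaps in `b`, then gaps in `a`.
gotoh_align <- function(a, b, params = align_params()) {
  sub <- substitution_matrix(params$matrix)
  open <- params$gap_open
  ext <- params$gap_extend
  av <- if (nzchar(a)) seq_chars(a) else character(0)
  bv <- if (nzchar(b)) seq_chars(b) else character(0)
  n <- length(av)
  m <- length(bv)
  if (n == 0 && m == 0) return(list(score = 0, a = "", b = ""))
  if (n == 0) {
    return(list(score = -(open + ext * m),
                a = strrep(GAP, m), b = b))
  }
  if (m == 0) {
    return(list(score = -(open + ext * n),
                a = a, b = strrep(GAP, n)))
  }

  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  X[2:(n + 1), 1] <- -(open + ext * seq_len(n))
  Y[1, 2:(m + 1)] <- -(open + ext * seq_len(m))
  S <- sub[av, bv, drop = FALSE]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- S[i, j] + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             X[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])

  # traceback
  ga <- character(0)
  gb <- character(0)
  i <- n
  j <- m
  state <- c("M", "X", "Y")[which.max(c(M[n + 1, m + 1], X[n + 1, m + 1],
                                        Y[n + 1, m + 1]))]
  while (i > 0 || j > 0) {
    if (state == "M") {
      ga <- c(av[i], ga)
      gb <- c(bv[j], gb)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      target <- M[i + 1, j + 1] - S[i, j]
      state <- c("M", "X", "Y")[which(abs(prev - target) < 1e-9)[1]]
      i <- i - 1
      j <- j - 1
    } else if (state == "X") {
      ga <- c(av[i], ga)
      gb <- c(GAP, gb)
      val <- X[i + 1, j + 1]
      cand <- c(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                Y[i, j + 1] - open - ext)
      state <- c("M", "X", "Y")[which(abs(cand - val) < 1e-9)[1]]
      i <- i - 1
    } else {
      ga <- c(GAP, ga)
      gb <- c(bv[j], gb)
      val <- Y[i + 1, j + 1]
      cand <- c(M[i + 1, j] - open - ext, X[i + 1, j] - open - ext,
                Y[i + 1, j] - ext)
      state <- c("M", "X", "Y")[which(abs(cand - val) < 1e-9)[1]]
      j <- j - 1
    }
  }
  list(score = score, a = paste(ga, collapse = ""),
       b = paste(gb, collapse = ""))
}

# Score (not alignment) of the optimal global pairwise alignment.
gotoh_score <- function(a, b, params = align_params()) {
  gotoh_align(a, b, params)$score
}

#' Sum-of-pairs score of a gapped block
#'
#' Scores a multiple alignment as the sum over all sequence pairs of the
#' induced pairwise alignment score: columns where both rows carry a gap are
#' dropped for that pair, residue pairs score by the substitution matrix, and
#' every maximal gap run costs `gap_open + length * gap_extend`.
#'
#' @param rows Character vector of equal-width gapped sequences.
#' @param params An [align_params()].
#' @return A single numeric score.
#' @export
sum_of_pairs_score <- function(rows, params = align_params()) {
  if (length(rows) < 2) return(0)
  widths <- unique(nchar(rows))
  if (length(widths) != 1) abort("All rows must have equal gapped width.")
  sub <- substitution_matrix(params$matrix)
  chars <- lapply(rows, seq_chars)
  total <- 0
  for (i in seq_along(rows)[-length(rows)]) {
    for (j in (i + 1):length(rows)) {
      total <- total + pair_alignment_score(chars[[i]], chars[[j]], sub,
                                            params$gap_open,
                                            params$gap_extend)
    }
  }
  total
}

# Affine score of one induced pairwise alignment given as character vectors.
pair_alignment_score <- function(x, y, sub, open, ext) {
  keep <- !(x == GAP & y == GAP)
  x <- x[keep]
  y <- y[keep]
  if (!length(x)) return(0)
  gx <- x == GAP
  gy <- y == GAP
  res <- !gx & !gy
  s <- 0
  if (any(res)) s <- s + sum(sub[cbind(x[res], y[res])])
  runs <- function(g) {
    if (!any(g)) return(c(0L, 0L))  # n_runs, n_positions
    r <- rle(g)
    c(sum(r$values), sum(r$lengths[r$values]))
  }
  rx <- runs(gx)
  ry <- runs(gy)
  s - open * (rx[1] + ry[1]) - ext * (rx[2] + ry[2])
}
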