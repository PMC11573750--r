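# Plaintext recurrent kernel network (RKN) forward pass in double precision:
# the correctness oracle for private inference and a standalone scorer.
#
# An RKN scores a protein sequence against q learned k-length motif templates
# (anchor points). At position t and motif level j it computes a per-anchor
# similarity b_j[t] = exp(alpha * (<z_{j,.,i}, x_t> - 1)) between the one-hot
# character x_t and the j-th character of each anchor, then updates the
# running k-mer embedding with the gap-decayed recurrence
#   c_j[t] = lambda * c_j[t-1] + b_j[t] * c_{j-1}[t-1],   c_0 = 1.
# The final embedding c_k[|x|] is whitened by the inverse square root of the
# anchor gram matrix and scored by a linear classifier.

#' Standard amino-acid alphabet used for one-hot encoding
#' @export
AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct an RKN model object
#'
#' @param Z anchor tensor as a `(k*q) x A` matrix, row `(j-1)*q + i` holding
#'   the j-th position of anchor i (A = alphabet size); every row must have
#'   unit Euclidean norm so that similarities stay in `[-1, 1]` and the
#'   exponential powers in `[-2*alpha, 0]`
#' @param alpha similarity scale (> 0)
#' @param lambda gap/decay factor in `[0, 1]`
#' @param G symmetric `q x q` inverse square root of the anchor gram matrix
#' @param w classifier weight vector, length q
#' @param beta classifier bias (scalar)
#' @param k,q motif length and number of anchors
#' @param alphabet character vector (default the 20 standard amino acids)
#' @return an object of class `rkn_model`
#' @export
rkn_model <- function(Z, alpha, lambda, G, w, beta, k, q,
                      alphabet = AA_ALPHABET20) {
  m <- structure(list(Z = Z, alpha = alpha, lambda = lambda, G = G, w = w,
                      beta = beta, k = as.integer(k), q = as.integer(q),
                      alphabet = alphabet),
                 class = "rkn_model")
  validate_rkn_model(m)
  m
}

validate_rkn_model <- function(m) {
  A <- length(m$alphabet)
  if (!is.matrix(m$Z) || nrow(m$Z) != m$k * m$q || ncol(m$Z) != A)
    stop("Z must be a (k*q) x |alphabet| matrix")
  norms <- sqrt(rowSums(m$Z^2))
  if (any(abs(norms - 1) > 1e-8))
    stop("anchor rows must have unit norm")
  if (!is.matrix(m$G) || any(dim(m$G) != m$q) ||
      max(abs(m$G - t(m$G))) > 1e-8)
    stop("G must be a symmetric q x q matrix")
  if (length(m$w) != m$q) stop("w must have length q")
  if (m$alpha <= 0) stop("alpha must be positive")
  if (m$lambda < 0 || m$lambda > 1) stop("lambda must lie in [0, 1]")
  invisible(m)
}

#' @export
print.rkn_model <- function(x, ...) {
  cat(sprintf("<rkn_model> q = %d anchors, k = %d, alpha = %.3g, lambda = %.3g\n",
              x$q, x$k, x$alpha, x$lambda))
  invisible(x)
}

#' One-hot encode a protein sequence
#'
#' @param sequence a character string over the model alphabet (or a vector of
#'   single characters)
#' @param alphabet character vector of valid residues
#' @param unknown `"error"` (default) rejects non-standard residues
#'   (B, Z, X, U, O, ...); `"zero"` maps them to an all-zero row
#' @return a `length(sequence) x length(alphabet)` 0/1 matrix; each row sums
#'   to 1 (or 0 for unknowns under `unknown = "zero"`)
#' @export
one_hot_encode <- function(sequence, alphabet = AA_ALPHABET20,
                           unknown = c("error", "zero")) {
  unknown <- match.arg(unknown)
  chars <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  if (length(chars) == 0L) stop("empty sequence")
  idx <- match(chars, alphabet)
  if (anyNA(idx) && unknown == "error")
    stop("unknown residue(s): ", paste(unique(chars[is.na(idx)]), collapse = ", "))
  out <- matrix(0, nrow = length(chars), ncol = length(alphabet))
  keep <- !is.na(idx)
  out[cbind(which(keep), idx[keep])] <- 1
  out
}

#' Per-position anchor similarities
#'
#' The gray-box computation of one RKN neuron: for a single one-hot row
#' `x_t`, returns `b[t] = exp(alpha * (Z x_t - 1))`, the similarity of the
#' character to the j-th character of each anchor, for all `k * q`
#' (level, anchor) pairs (row `(j-1)*q + i`).
#'
#' @param model an [rkn_model()]
#' @param x_t a length-|alphabet| one-hot vector (one row of
#'   [one_hot_encode()])
#' @return numeric vector of length `k * q`, values in `(0, 1]`
#' @export
rkn_similarity <- function(model, x_t) {
  exp(model$alpha * (as.numeric(model$Z %*% x_t) - 1))
}

#' Plaintext RKN forward pass
#'
#' Double-precision evaluation of the RKN circuit; deterministic, and the
#' oracle against which private inference is verified.
#'
#' @param model an [rkn_model()]
#' @param seq a sequence string or a one-hot matrix from [one_hot_encode()]
#' @return list with `prediction` (the classifier score `<w, psi> + beta`),
#'   `mapping` (the whitened final embedding `psi = G c_k`), and `ck`
#'   (the raw final embedding)
#' @export
rkn_forward <- function(model, seq) {
  x <- if (is.character(seq)) one_hot_encode(seq, model$alphabet) else seq
  if (ncol(x) != length(model$alphabet)) stop("alphabet size mismatch")
  k <- model$k; q <- model$q
  cmat <- matrix(0, nrow = k + 1L, ncol = q)
  cmat[1L, ] <- 1
  for (t in seq_len(nrow(x))) {
    dots <- model$Z %*% x[t, ]                       # (k*q) similarities
    b <- exp(model$alpha * (dots - 1))
    bmat <- matrix(b, nrow = k, ncol = q, byrow = TRUE)
    cmat[-1L, ] <- model$lambda * cmat[-1L, , drop = FALSE] +
      bmat * cmat[-(k + 1L), , drop = FALSE]
  }
  ck <- cmat[k + 1L, ]
  psi <- as.numeric(model$G %*% ck)
  list(prediction = sum(model$w * psi) + model$beta, mapping = psi, ck = ck)
}

# ---- model container I/O ----------------------------------------------------

#' Write an RKN model to a directory of plain-text files
#'
#' One whitespace-delimited text matrix per parameter (`Z.txt`, `G.txt`,
#' `w.txt`) plus a JSON manifest (`manifest.json`) recording q, k, alpha,
#' lambda, beta and the alphabet.
#'
#' @param model an [rkn_model()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_model_dir <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(model$Z, file.path(dir, "Z.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(model$G, file.path(dir, "G.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(matrix(model$w, ncol = 1), file.path(dir, "w.txt"),
                     row.names = FALSE, col.names = FALSE)
  manifest <- list(q = model$q, k = model$k, alpha = model$alpha,
                   lambda = model$lambda, beta = model$beta,
                   alphabet = paste(model$alphabet, collapse = ""))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an RKN model written by [write_model_dir()]
#'
#' @param dir directory containing `manifest.json`, `Z.txt`, `G.txt`, `w.txt`
#' @return an [rkn_model()]
#' @export
read_model_dir <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  Z <- as.matrix(utils::read.table(file.path(dir, "Z.txt")))
  G <- as.matrix(utils::read.table(file.path(dir, "G.txt")))
  w <- as.numeric(utils::read.table(file.path(dir, "w.txt"))[[1]])
  dimnames(Z) <- NULL; dimnames(G) <- NULL
  rkn_model(Z, man$alpha, man$lambda, G, w, man$beta, man$k, man$q,
            alphabet = strsplit(man$alphabet, "")[[1]])
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs named character vector
#' @param path output file
#' @export
write_fasta_sequences <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
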