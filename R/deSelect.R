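# Rough-set subset-entropy feature/channel selection.
#
# For a decision table (U, C u D) and a subset P of the condition
# attributes C, the subset entropy is
#   E(P | U + C) = -(1/|U|) sum_x log2( |[x]_C n [x]_P| / |[x]_P| )
# which, because [x]_C is always contained in [x]_P, simplifies to
#   E(P | U + C) = -(1/|U|) sum_x log2( |[x]_C| / |[x]_P| ).
# E is 0 exactly when U/P = U/C and at most log2 |U|.

#' Discretize a feature matrix into a decision table
#'
#' Maps every feature column to integer codes 0..nBins-1 by equal-frequency
#' (quantile) or equal-width binning; the decision attribute is the emotion
#' label. A constant column collapses to a single bin with a warning.
#'
#' @param matrix a \linkS4class{FeatureMatrix}, or a plain numeric matrix
#'   together with \code{labels}.
#' @param nBins number of bins (>= 2), default 10.
#' @param method "equal_frequency" (default) or "equal_width".
#' @param labels decision values when \code{matrix} is a bare matrix.
#' @return A \linkS4class{DecisionTable}.
#' @examples
#' x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
#' discretizeFeatures(x, nBins = 4, labels = rep(c("negative", "positive"), 5))
#' @export
discretizeFeatures <- function(matrix, nBins = 10L,
                               method = c("equal_frequency", "equal_width"),
                               labels = NULL) {
  method <- match.arg(method)
  if (nBins < 2L) stop("nBins must be >= 2")
  if (is(matrix, "FeatureMatrix")) {
    vals <- featureValues(matrix)
    labels <- unitInfo(matrix)$label
  } else {
    vals <- as.matrix(matrix)
    if (is.null(labels)) stop("labels required for a bare matrix")
  }
  codes <- vapply(seq_len(ncol(vals)), function(j) {
    discretizeColumn(vals[, j], nBins, method, colnames(vals)[j])
  }, integer(nrow(vals)))
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = nrow(vals))
  colnames(codes) <- if (is.null(colnames(vals)))
    sprintf("a%03d", seq_len(ncol(vals))) else colnames(vals)
  DecisionTable(codes, labels)
}

discretizeColumn <- function(x, nBins, method, name = NULL) {
  if (diff(range(x)) == 0) {
    warning(sprintf("constant column%s collapses to one bin",
                    if (is.null(name)) "" else paste0(" '", name, "'")))
    return(rep(0L, length(x)))
  }
  breaks <- if (method == "equal_width") {
    seq(min(x), max(x), length.out = nBins + 1L)
  } else {
    unique(stats::quantile(x, probs = seq(0, 1, length.out = nBins + 1L),
                           names = FALSE))
  }
  if (length(breaks) < 2L) return(rep(0L, length(x)))
  as.integer(cut(x, breaks, include.lowest = TRUE, labels = FALSE)) - 1L
}

#' Indiscernibility partition of a decision table
#'
#' Objects fall in the same block iff they agree on every attribute in
#' \code{attrs}. An empty attribute set yields the single-block (trivial)
#' partition. Blocks are ordered by their first member.
#'
#' @param table a \linkS4class{DecisionTable}.
#' @param attrs character names (or integer indices) of condition
#'   attributes, or \code{"decision"} for the decision attribute.
#' @return A \linkS4class{Partition}.
#' @export
partitionBy <- function(table, attrs) {
  stopifnot(is(table, "DecisionTable"))
  n <- nrow(table@values)
  if (length(attrs) == 0L)
    return(new("Partition", blocks = list(seq_len(n)), n = as.integer(n)))
  if (identical(attrs, "decision")) {
    key <- as.integer(table@decision)
  } else {
    if (is.numeric(attrs)) attrs <- colnames(table@values)[attrs]
    missing <- setdiff(attrs, colnames(table@values))
    if (length(missing))
      stop("unknown attribute(s): ", paste(missing, collapse = ", "))
    sub <- table@values[, attrs, drop = FALSE]
    key <- blockIds(sub)
  }
  blocks <- split(seq_len(n), key)
  blocks <- blocks[order(vapply(blocks, `[`, integer(1), 1L))]
  names(blocks) <- NULL
  new("Partition", blocks = blocks, n = as.integer(n))
}

# integer block id per row, equal iff rows identical across columns
blockIds <- function(m) {
  if (ncol(m) == 0L) return(rep(1L, nrow(m)))
  key <- do.call(paste, c(lapply(seq_len(ncol(m)), function(j) m[, j]),
                          sep = "\r"))
  match(key, key)
}

#' Subset entropy of an attribute subset (fast path)
#'
#' Computes \eqn{E(P|U \oplus C)} in bits through equivalence-class sizes:
#' each object contributes \eqn{\log_2(|[x]_P| / |[x]_C|)}, averaged over
#' the universe. Returns 0 exactly when P induces the same partition as C.
#'
#' @param table a \linkS4class{DecisionTable}.
#' @param P character names (or integer indices) of the attributes in P;
#'   must be a subset of C.
#' @return A \linkS4class{DEScore}.
#' @examples
#' dt <- DecisionTable(cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1)),
#'                     rep(c("negative", "positive"), 2))
#' deSubsetEntropy(dt, c("a", "b"))   # 0: P = C
#' deSubsetEntropy(dt, "a")           # 1 bit
#' @export
deSubsetEntropy <- function(table, P) {
  stopifnot(is(table, "DecisionTable"))
  n <- nrow(table@values)
  if (n == 0L) stop("empty universe")
  if (is.numeric(P)) P <- colnames(table@values)[P]
  missing <- setdiff(P, colnames(table@values))
  if (length(missing))
    stop("P must be a subset of C; unknown: ", paste(missing, collapse = ", "))
  idC <- blockIds(table@values)
  idP <- blockIds(table@values[, P, drop = FALSE])
  sizeC <- tabulate(idC)[idC]
  sizeP <- tabulate(idP)[idP]
  val <- mean(log2(sizeP / sizeC))
  new("DEScore", subset = as.character(P), value = val)
}

#' Subset entropy by explicit double loop (oracle twin)
#'
#' Direct evaluation of the defining sum: for every object the
#' indiscernibility classes \eqn{[x]_C} and \eqn{[x]_P} are materialised as
#' explicit sets and the ratio \eqn{|[x]_C \cap [x]_P| / |[x]_P|} is formed.
#' Intended as an independent cross-check of
#' \code{\link{deSubsetEntropy}} at small |U|.
#'
#' @param table a \linkS4class{DecisionTable} with at most 512 objects.
#' @param P attribute subset, as in \code{\link{deSubsetEntropy}}.
#' @return A \linkS4class{DEScore}.
#' @export
deSubsetEntropyBruteforce <- function(table, P) {
  stopifnot(is(table, "DecisionTable"))
  n <- nrow(table@values)
  if (n == 0L) stop("empty universe")
  if (n > 512L) stop("brute-force oracle limited to |U| <= 512")
  if (is.numeric(P)) P <- colnames(table@values)[P]
  missing <- setdiff(P, colnames(table@values))
  if (length(missing))
    stop("P must be a subset of C; unknown: ", paste(missing, collapse = ", "))
  V <- table@values
  VP <- V[, P, drop = FALSE]
  total <- 0
  for (x in seq_len(n)) {
    classC <- which(vapply(seq_len(n), function(y)
      all(V[y, ] == V[x, ]), logical(1)))
    classP <- which(vapply(seq_len(n), function(y)
      all(VP[y, ] == VP[x, ]), logical(1)))
    total <- total + log2(length(intersect(classC, classP)) / length(classP))
  }
  new("DEScore", subset = as.character(P), value = -total / n)
}

#' Rank channels by subset entropy
#'
#' Scores every channel by the subset entropy of its feature block against
#' the full condition set. Each channel's feature block is first summarised
#' to a few attributes --- the leading principal component of each of
#' \code{nComponents} disjoint, interleaved feature chunks --- then
#' discretized; the universe is the set of recordings. The chunked summary
#' is what makes the statistic informative: when a channel carries coherent
#' class structure, every chunk's leading component reflects that same
#' structure, the discretized attributes agree, and the channel's partition
#' stays coarse (large subset entropy); a noise channel's chunks are
#' independent, their joint partition collapses towards singletons, and the
#' entropy tends to zero. (The joint partition over hundreds of raw
#' discretized columns degenerates to singletons at any realistic sample
#' size, which is why the raw block is not used directly.)
#' With \code{direction = "high"} (default) channels carrying a large
#' information boundary rank first; \code{direction = "low"} ranks the most
#' C-faithful (refined) channels first. Ties break by ascending channel
#' index.
#'
#' @param matrix a \linkS4class{FeatureMatrix} with per-(recording, channel)
#'   units.
#' @param nBins discretization bins (default 3).
#' @param nComponents feature chunks (attributes) per channel block
#'   (default 3).
#' @param budget how many channels to select (default: all, i.e. ranking
#'   only).
#' @param direction "high" or "low" score-first ordering.
#' @return A \linkS4class{ChannelRanking}.
#' @export
rankChannels <- function(matrix, nBins = 3L, nComponents = 3L,
                         budget = NULL, direction = c("high", "low")) {
  direction <- match.arg(direction)
  stopifnot(is(matrix, "FeatureMatrix"))
  info <- unitInfo(matrix)
  vals <- featureValues(matrix)
  channels <- sort(unique(info$channel))
  recs <- unique(info$recording)
  degenerate <- length(channels) < 2L
  if (degenerate)
    warning("single channel: ranking is degenerate")
  # per-channel chunked-PC summary, one row per recording
  pcCols <- list()
  for (ch in channels) {
    sel <- info$channel == ch
    block <- vals[sel, , drop = FALSE]
    rownames(block) <- info$recording[sel]
    block <- block[recs, , drop = FALSE]
    keep <- which(apply(block, 2, stats::sd) > 0)
    m <- max(1L, min(nComponents, length(keep), nrow(block) - 1L))
    chunks <- split(keep, rep_len(seq_len(m), length(keep)))
    pcs <- vapply(chunks, function(cols) {
      if (length(cols) == 0L) return(numeric(nrow(block)))
      stats::prcomp(block[, cols, drop = FALSE], center = TRUE,
                    scale. = TRUE, rank. = 1L)$x[, 1]
    }, numeric(nrow(block)))
    if (!is.matrix(pcs)) pcs <- matrix(pcs, nrow = nrow(block))
    colnames(pcs) <- sprintf("ch%03d_pc%d", ch, seq_len(ncol(pcs)))
    pcCols[[as.character(ch)]] <- pcs
  }
  allPcs <- do.call(cbind, pcCols)
  recLab <- info$label[match(recs, info$recording)]
  suppressWarnings(
    dt <- discretizeFeatures(allPcs, nBins = nBins, labels = recLab))
  scores <- vapply(channels, function(ch) {
    P <- grep(sprintf("^ch%03d_", ch), colnames(dt@values), value = TRUE)
    deSubsetEntropy(dt, P)@value
  }, numeric(1))
  ord <- if (direction == "high") order(-scores, channels)
         else order(scores, channels)
  if (is.null(budget)) budget <- length(channels)
  selected <- sort(channels[ord][seq_len(min(budget, length(channels)))])
  new("ChannelRanking", channels = as.integer(channels[ord]),
      scores = scores[ord], selected = as.integer(selected),
      direction = direction, degenerate = degenerate)
}

#' Reduce a feature matrix to the selected channels
#'
#' Keeps the units belonging to the top-\code{budget} channels of the
#' ranking (channel order preserved).
#'
#' @param matrix a \linkS4class{FeatureMatrix}.
#' @param budget number of channels to keep (>= 1).
#' @param ranking optional precomputed \linkS4class{ChannelRanking};
#'   computed from \code{matrix} when missing.
#' @param ... passed to \code{\link{rankChannels}}.
#' @return A reduced \linkS4class{FeatureMatrix}.
#' @export
selectFeatures <- function(matrix, budget, ranking = NULL, ...) {
  stopifnot(is(matrix, "FeatureMatrix"), budget >= 1)
  info <- unitInfo(matrix)
  nCh <- length(unique(info$channel))
  if (budget > nCh)
    stop(sprintf("budget (%d) exceeds available channels (%d)", budget, nCh))
  if (budget == nCh) return(matrix)
  if (is.null(ranking)) ranking <- rankChannels(matrix, budget = budget, ...)
  keepCh <- ranking@channels[seq_len(budget)]
  keep <- info$channel %in% keepCh
  new("FeatureMatrix", matrix[, keep])
}

#' Export a decision table as tab-separated values
#'
#' Writes a TSV with a header row: the condition attributes followed by a
#' final \code{decision} column.
#'
#' @param table a \linkS4class{DecisionTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
exportDecisionTable <- function(table, path) {
  stopifnot(is(table, "DecisionTable"))
  df <- as.data.frame(table@values)
  df$decision <- as.character(table@decision)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
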