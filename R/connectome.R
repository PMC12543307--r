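#' Construct a Connectome
#'
#' @param weights n x n symmetric non-negative weight matrix, zero diagonal.
#' @param tractLengths n x n symmetric tract-length matrix (mm), positive
#'   wherever \code{weights > 0}.
#' @param labels optional region names; defaults to \code{R1..Rn}.
#' @return a validated \code{\linkS4class{Connectome}}.
#' @export
connectome <- function(weights, tractLengths, labels = NULL) {
  if (is.null(labels)) labels <- paste0("R", seq_len(nrow(weights)))
  new("Connectome", weights = unname(as.matrix(weights)),
      tractLengths = unname(as.matrix(tractLengths)), labels = labels)
}

#' Generate a synthetic modular connectome with connector hubs
#'
#' Builds a weighted, undirected connectome emulating the gross organisation
#' of DTI-derived cortical connectomes: dense modules with sparser
#' inter-module connections, a fraction of connector hubs with elevated
#' inter-module degree, log-normal weight magnitudes, and tract lengths given
#' by Euclidean distances between random node positions in a 3-D box scaled
#' so the mean connected tract length is ~70 mm (brain-plausible, so derived
#' delay/velocity numbers are realistic). Weights are scaled so the mean row
#' sum is 1; they are \emph{not} row-normalised per node, since the network
#' models apply the global coupling to the raw matrix.
#'
#' @param nNodes number of regions (>= 4).
#' @param nModules number of modules (1 .. nNodes/2).
#' @param hubFraction fraction of nodes promoted to connector hubs
#'   (0 <= hubFraction < 0.5).
#' @param weightDispersion log-SD of the log-normal weight magnitudes;
#'   0 gives equal weights within each block type.
#' @param seed integer seed; identical seeds give bit-identical connectomes.
#' @param pInter baseline inter-module connection probability.
#' @param pInterHub inter-module connection probability for hub nodes.
#' @param interScale ratio of median inter- to intra-module weight.
#' @param meanLength target mean connected tract length (mm).
#' @return a \code{\linkS4class{Connectome}}.
#' @examples
#' con <- generateConnectome(40, nModules = 4, hubFraction = 0.1,
#'                           weightDispersion = 0.5, seed = 7)
#' con
#' @export
generateConnectome <- function(nNodes, nModules = 1, hubFraction = 0,
                               weightDispersion = 0.5, seed = 1,
                               pInter = 0.3, pInterHub = 0.9,
                               interScale = 1 / 3, meanLength = 70) {
  if (nNodes != round(nNodes) || nNodes < 4)
    stop("nNodes must be an integer >= 4")
  nNodes <- as.integer(nNodes)
  if (nModules < 1 || nModules > nNodes / 2)
    stop("need 1 <= nModules <= nNodes/2")
  if (hubFraction < 0 || hubFraction >= 0.5)
    stop("hubFraction must lie in [0, 0.5)")

  set.seed(seed)
  module <- sort(rep_len(seq_len(nModules), nNodes))
  nHubs <- floor(hubFraction * nNodes)
  hubs <- if (nHubs > 0) sample(nNodes, nHubs) else integer(0)

  W <- matrix(0, nNodes, nNodes)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  sameMod <- module[ut[, 1]] == module[ut[, 2]]
  pEdge <- ifelse(sameMod, 1,
                  ifelse(ut[, 1] %in% hubs | ut[, 2] %in% hubs,
                         pInterHub, pInter))
  present <- runif(nrow(ut)) < pEdge
  scale <- ifelse(sameMod, 1, interScale)
  w <- scale * exp(rnorm(nrow(ut), 0, weightDispersion))
  w[!present] <- 0
  W[ut] <- w
  W <- W + t(W)
  W <- W / mean(rowSums(W))            # mean row sum 1 (documented convention)

  # node positions: modules are spatial clusters (module centres spread in a
  # cube, members jittered around them), so intra-module tracts are short and
  # inter-module tracts long, as in real cortex; the cube is scaled so the
  # mean pairwise distance is meanLength
  centres <- matrix(runif(3 * nModules), ncol = 3)
  pos <- centres[module, , drop = FALSE] +
    matrix(rnorm(3 * nNodes, 0, 0.12), ncol = 3)
  Dm <- as.matrix(stats::dist(pos))
  Dm <- Dm * meanLength / mean(Dm[upper.tri(Dm)])
  connectome(W, Dm, paste0("R", seq_len(nNodes)))
}

#' Shuffle a connectome's connections
#'
#' Permutes the off-diagonal upper-triangle weight entries uniformly at
#' random (mirrored to preserve symmetry), destroying topology while exactly
#' preserving the multiset of edge weights -- so the complexity of the weight
#' distribution itself is unchanged. Tract lengths are permuted with the same
#' permutation so connected pairs keep positive lengths.
#'
#' @param con a \code{\linkS4class{Connectome}}.
#' @param seed integer seed.
#' @return a shuffled \code{Connectome}; the input is not modified.
#' @export
shuffleConnectome <- function(con, seed = 1) {
  stopifnot(is(con, "Connectome"))
  set.seed(seed)
  W <- con@weights; L <- con@tractLengths
  ut <- upper.tri(W)
  p <- sample(sum(ut))
  W2 <- W; L2 <- L
  W2[ut] <- W[ut][p]
  L2[ut] <- L[ut][p]
  W2[lower.tri(W2)] <- t(W2)[lower.tri(W2)]
  L2[lower.tri(L2)] <- t(L2)[lower.tri(L2)]
  connectome(W2, L2, con@labels)
}

#' Apply a focal structural lesion
#'
#' Removes all connections to and from one node by zeroing its row and column
#' of the weight matrix; everything else (including tract lengths) is left
#' untouched and the input object is not modified.
#'
#' @param con a \code{\linkS4class{Connectome}}.
#' @param node node index in 1..nNodes.
#' @return the lesioned \code{Connectome}.
#' @export
applyLesion <- function(con, node) {
  stopifnot(is(con, "Connectome"))
  n <- nNodes(con)
  if (node != round(node) || node < 1 || node > n)
    stop(sprintf("node must be an integer in 1..%d", n))
  W <- con@weights
  W[node, ] <- 0
  W[, node] <- 0
  connectome(W, con@tractLengths, con@labels)
}

#' Derive conduction delays from tract lengths
#'
#' Chooses the single global conduction velocity such that the mean of
#' \code{tractLength / velocity} over connected node pairs equals
#' \code{meanDelay}, and returns the full delay matrix. \code{meanDelay = 0}
#' is treated as the zero-delay (infinite-velocity) limit.
#'
#' @param con a \code{\linkS4class{Connectome}}.
#' @param meanDelay target mean delay over connected pairs (ms).
#' @return a \code{\linkS4class{DelayMatrix}}.
#' @export
delaysFromLengths <- function(con, meanDelay) {
  stopifnot(is(con, "Connectome"))
  if (meanDelay < 0) stop("meanDelay must be >= 0")
  W <- con@weights; L <- con@tractLengths
  if (meanDelay == 0)
    return(new("DelayMatrix", delays = matrix(0, nrow(W), ncol(W)),
               meanDelay = 0, velocity = Inf))
  conn <- W > 0
  diag(conn) <- FALSE
  if (!any(conn) || all(L[conn] == 0))
    stop("cannot realise a positive meanDelay with all-zero tract lengths")
  mL <- mean(L[conn])                  # mm
  velocity <- mL / meanDelay           # mm/ms == m/s
  new("DelayMatrix", delays = L / velocity, meanDelay = meanDelay,
      velocity = velocity)
}

#' Write / read a connectome as TSV
#'
#' Plain-text interchange: two square TSV matrices (weights and tract
#' lengths) with a header row of region labels. The reader validates all
#' connectome invariants on load.
#'
#' @param con a \code{\linkS4class{Connectome}}.
#' @param weightsFile,lengthsFile file paths.
#' @return \code{writeConnectomeTSV} returns the paths invisibly;
#'   \code{readConnectomeTSV} returns a validated \code{Connectome}.
#' @export
writeConnectomeTSV <- function(con, weightsFile, lengthsFile) {
  stopifnot(is(con, "Connectome"))
  w <- con@weights; colnames(w) <- con@labels
  l <- con@tractLengths; colnames(l) <- con@labels
  write.table(w, weightsFile, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(l, lengthsFile, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(weightsFile, lengthsFile))
}

#' @rdname writeConnectomeTSV
#' @export
readConnectomeTSV <- function(weightsFile, lengthsFile) {
  w <- as.matrix(read.delim(weightsFile, check.names = FALSE))
  l <- as.matrix(read.delim(lengthsFile, check.names = FALSE))
  connectome(w, l, colnames(w))
}
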