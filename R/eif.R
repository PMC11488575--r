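#' Isolation-forest path-length normalizer c(n)
#'
#' Expected path length of an unsuccessful search in a binary search tree
#' over n points, in the asymptotic form used by isolation forests:
#' `c(n) = 2*(ln(n - 1) + gamma) - 2*(n - 1)/n` with Euler-Mascheroni gamma,
#' and `c(1) = c(0) = 0` (a single point cannot be split).
#'
#' @param n Integer vector of point counts (n >= 1).
#' @return Numeric vector of normalizers.
#' @export
harmonicC <- function(n) {
  if (any(n < 1)) stop("n must be >= 1")
  out <- numeric(length(n))
  big <- n >= 2
  nb <- n[big]
  out[big] <- 2 * (log(nb - 1) + .EULER_GAMMA) - 2 * (nb - 1) / nb
  out
}

.cTable <- function(psi) {
  # ctab[k + 1] = c(k) for k = 0..psi, consumed 0-based by the C++ scorer
  c(0, 0, harmonicC(seq(2L, max(2L, psi))))[seq_len(psi + 1L)]
}

#' Fit an extended isolation forest
#'
#' Grows `nTrees` isolation trees, each on a uniform subsample (without
#' replacement) of `psi` points. Every internal node cuts with a random
#' hyperplane: the normal vector is uniform on the unit sphere and the
#' intercept point is uniform inside the node's bounding box (the fully
#' extended construction; cuts are not axis-parallel). Recursion stops at
#' `ceiling(log2(psi))`, at a single point, or when all points at a node are
#' identical.
#'
#' @param points Numeric matrix (n x d) of training points; d >= 2.
#' @param nTrees Number of trees (default 200).
#' @param psi Subsample size per tree; clamped to n with a warning if larger.
#' @param seed Integer seed; expanded into independent per-tree streams, so
#'   the forest is bit-reproducible.
#' @return An [EifModel-class].
#' @export
fitEif <- function(points, nTrees = 200L, psi, seed = 1L) {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("non-finite training points")
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 training points")
  psi <- as.integer(round(psi))
  if (psi > n) {
    warning("psi (", psi, ") > n (", n, "); clamping to n")
    psi <- n
  }
  if (psi < 2L) stop("psi must be >= 2")
  maxDepth <- as.integer(ceiling(log2(psi)))
  trees <- eif_fit_cpp(points, as.integer(nTrees), psi, maxDepth,
                       as.numeric(seed))
  methods::new("EifModel", trees = trees, nTrees = as.integer(nTrees),
               psi = psi, maxDepth = maxDepth, d = ncol(points),
               seed = as.numeric(seed))
}

#' Anomaly scores from a fitted forest
#'
#' For each query point the isolation path length per tree is the number of
#' edges traversed to its leaf plus `harmonicC(leaf size)`; the anomaly score
#' is `s = 2^(-meanPath / c(psi))`, so points that are isolated quickly score
#' close to 1 and deep, well-embedded points score below 0.5.
#'
#' @param model An [EifModel-class].
#' @param points Numeric matrix (m x d) of query points (a vector is treated
#'   as one point).
#' @return data.frame with columns `score` in (0, 1] and `mean_path`.
#' @export
anomalyScore <- function(model, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  points <- as.matrix(points)
  if (ncol(points) != model@d)
    stop("query dimensionality differs from the model")
  ctab <- .cTable(model@psi)
  mp <- eif_path_cpp(model@trees, points, ctab)
  cpsi <- harmonicC(model@psi)
  data.frame(score = 2^(-mp / cpsi), mean_path = mp)
}

# ---- serialization ----------------------------------------------------------

#' Serialize / restore an EifModel as JSON
#'
#' Versioned plain-text dump of the full tree ensemble; `eifFromJson()`
#' round-trips to an identical model (identical scores).
#'
#' @param model An [EifModel-class].
#' @param path Optional file path; if NULL the JSON string is returned.
#' @return `eifToJson`: the path (invisibly) or a JSON string.
#' @export
eifToJson <- function(model, path = NULL) {
  obj <- list(
    format = "ribopause-eif", version = 1L,
    nTrees = model@nTrees, psi = model@psi, maxDepth = model@maxDepth,
    d = model@d, seed = model@seed,
    trees = lapply(model@trees, function(tr) list(
      normal = tr$normal, point = tr$point,
      left = tr$left, right = tr$right, size = tr$size)))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname eifToJson
#' @param json A JSON string or path to a file written by [eifToJson()].
#' @return `eifFromJson`: an [EifModel-class].
#' @export
eifFromJson <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  obj <- jsonlite::fromJSON(paste(json, collapse = ""),
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (!identical(obj$format, "ribopause-eif"))
    stop("not a ribopause EIF dump")
  trees <- lapply(obj$trees, function(tr) {
    list(normal = .asMat(tr$normal, obj$d), point = .asMat(tr$point, obj$d),
         left = as.integer(tr$left), right = as.integer(tr$right),
         size = as.integer(tr$size))
  })
  methods::new("EifModel", trees = trees, nTrees = as.integer(obj$nTrees),
               psi = as.integer(obj$psi), maxDepth = as.integer(obj$maxDepth),
               d = as.integer(obj$d), seed = as.numeric(obj$seed))
}

.asMat <- function(m, d) {
  m <- as.matrix(m)
  if (ncol(m) != d) m <- matrix(as.numeric(m), ncol = d)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}
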