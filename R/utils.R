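#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Run code with a locally fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Otsu's threshold of a numeric array
#'
#' Histogram-based between-class variance maximization, as used to split the
#' bright dyed medium from the tablet foreground in the first frame.
#'
#' @param x numeric vector/matrix of intensities.
#' @param nbins number of histogram bins.
#' @return scalar threshold on the scale of `x`.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) stop("otsu_threshold: no finite values")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  mids <- (br[-1] + br[-(nbins + 1L)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  n <- w[nbins]; mu_t <- mu[nbins]
  w0 <- w[-nbins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (mu_t * w0[valid] - n * mu[-nbins][valid])^2 /
    (as.numeric(w0[valid]) * w1[valid])
  k <- which.max(bcv)
  (mids[k] + mids[k + 1L]) / 2
}

## Normalized blueness index: B - (R+G)/2 mapped from [-1,1] to [0,1].
## High for the brilliant-blue medium, low for undyed tablet matter.
blueness_index <- function(frame) {
  (frame[, , 3] - (frame[, , 1] + frame[, , 2]) / 2 + 1) / 2
}

## Euclidean RGB distance to a reference (medium) color, normalized to [0,1].
mediumness_index <- function(frame, medium_color) {
  d <- (frame[, , 1] - medium_color[1])^2 +
       (frame[, , 2] - medium_color[2])^2 +
       (frame[, , 3] - medium_color[3])^2
  sqrt(d) / sqrt(3)
}

luminance_index <- function(frame) {
  0.2126 * frame[, , 1] + 0.7152 * frame[, , 2] + 0.0722 * frame[, , 3]
}

## Run-length connected-component labelling (4-connectivity) of a logical
## matrix via row runs + union-find; efficient for blob-like foregrounds.
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  ## runs per column-major? operate row-wise: find runs along each row
  runs <- vector("list", nr)
  nrun <- 0L
  for (i in seq_len(nr)) {
    r <- mask[i, ]
    if (!any(r)) next
    d <- diff(c(FALSE, r, FALSE))
    st <- which(d == 1L); en <- which(d == -1L) - 1L
    runs[[i]] <- cbind(start = st, end = en, id = nrun + seq_along(st))
    nrun <- nrun + length(st)
  }
  if (nrun == 0L) return(list(labels = matrix(0L, nr, nc), n = 0L, sizes = integer(0)))
  parent <- seq_len(nrun)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  for (i in 2:nr) {
    a <- runs[[i - 1]]; b <- runs[[i]]
    if (is.null(a) || is.null(b)) next
    for (j in seq_len(nrow(b))) {
      ov <- which(a[, "start"] <= b[j, "end"] & a[, "end"] >= b[j, "start"])
      for (k in ov) union(a[k, "id"], b[j, "id"])
    }
  }
  root <- vapply(seq_len(nrun), find, integer(1))
  relab <- match(root, sort(unique(root)))
  labels <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    b <- runs[[i]]
    if (is.null(b)) next
    for (j in seq_len(nrow(b)))
      labels[i, b[j, "start"]:b[j, "end"]] <- relab[b[j, "id"]]
  }
  list(labels = labels, n = max(relab), sizes = tabulate(labels[labels > 0L], max(relab)))
}
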