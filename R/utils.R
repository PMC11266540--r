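#' @importFrom rlang %||% .data
#' @importFrom stats median qnorm rbinom rnorm rpois runif rexp rbeta rgamma
#'   setNames quantile sd cor pnorm pt complete.cases coef vcov glm binomial
#'   lm hclust as.dist cutree dist kmeans var plogis uniroot
#' @importFrom utils head
NULL

# Fan a single user seed out to per-component child seeds. Fixed offsets per
# component keep streams independent: adding a new component never perturbs
# the draws of existing ones. Kept below 2^31 - 1.
derive_seed <- function(seed, component) {
  offsets <- c(
    source_afs = 1L, ancestry = 2L, genotypes = 3L, enriched = 4L,
    ibd = 5L, phenotypes = 6L, covariates = 7L, clusters = 8L,
    external = 9L, noise = 10L
  )
  off <- offsets[[component]]
  as.integer((as.double(seed) * 48271 + off * 101027) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

canonical_pair <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}
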