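#' Wright's numerator relationship matrix by the tabular method
#'
#' Computes the additive (numerator) relationship matrix A from a pedigree
#' using the recursive tabular rules: processing individuals in an order
#' where parents precede offspring, \eqn{A_{ii} = 1 + A_{p_1 p_2}/2} and
#' \eqn{A_{ij} = (A_{j p_1} + A_{j p_2})/2} for previously processed j,
#' with unknown parents contributing zero (treated as unrelated, non-inbred
#' founders). The diagonal is 1 plus the inbreeding coefficient.
#'
#' @param pedigree Data frame with columns `id`, `parent1`, `parent2`
#'   (unknown parents as NA or "").
#' @return A symmetric numeric matrix with `id` dimnames.
#' @export
#' @examples
#' ped <- tibble::tibble(id = c("A", "B", "O"),
#'                       parent1 = c(NA, NA, "A"),
#'                       parent2 = c(NA, NA, "B"))
#' relationship_matrix(ped)["A", "O"]  # parent-offspring: 0.5
relationship_matrix <- function(pedigree) {
  pedigree <- as.data.frame(pedigree)
  need <- c("id", "parent1", "parent2")
  if (!all(need %in% names(pedigree)))
    stop("pedigree needs columns id, parent1, parent2", call. = FALSE)
  ids <- as.character(pedigree$id)
  if (anyDuplicated(ids))
    stop("duplicate pedigree ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  clean <- function(p) {
    p <- as.character(p)
    p[!is.na(p) & p == ""] <- NA_character_
    p
  }
  p1 <- clean(pedigree$parent1)
  p2 <- clean(pedigree$parent2)
  unknown_parent <- function(p) !is.na(p) & !(p %in% ids)
  if (any(unknown_parent(p1)) || any(unknown_parent(p2)))
    stop("parents not present in pedigree: ",
         paste(unique(c(p1[unknown_parent(p1)], p2[unknown_parent(p2)])),
               collapse = ", "), call. = FALSE)

  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  pi1 <- ifelse(is.na(p1), 0L, idx[p1])
  pi2 <- ifelse(is.na(p2), 0L, idx[p2])

  # Kahn topological order; a leftover individual sits on a cycle
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(pi1[i], pi2[i])) {
      if (p > 0) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n)
    stop("pedigree cycle involving: ",
         paste(ids[setdiff(seq_len(n), order)], collapse = ", "),
         call. = FALSE)

  A <- matrix(0, n, n, dimnames = list(ids, ids))
  done <- integer(0)
  for (i in order) {
    a1 <- pi1[i]; a2 <- pi2[i]
    if (length(done)) {
      v1 <- if (a1 > 0) A[done, a1] else 0
      v2 <- if (a2 > 0) A[done, a2] else 0
      A[done, i] <- A[i, done] <- 0.5 * (v1 + v2)
    }
    A[i, i] <- 1 + if (a1 > 0 && a2 > 0) 0.5 * A[a1, a2] else 0
    done <- c(done, i)
  }
  A
}

#' Normalize a relationship matrix to a correlation matrix
#'
#' \eqn{C_{ij} = A_{ij} / \sqrt{A_{ii} A_{jj}}}; the diagonal becomes
#' exactly 1 and the operation is idempotent.
#'
#' @param A Symmetric relationship matrix with positive diagonal.
#' @return Correlation matrix of the same dimension and dimnames.
#' @export
to_correlation <- function(A) {
  d <- diag(A)
  if (any(d <= 0))
    stop("relationship matrix has non-positive diagonal entries",
         call. = FALSE)
  C <- stats::cov2cor(A)
  diag(C) <- 1
  dimnames(C) <- dimnames(A)
  C
}

#' K-means clustering of genotypes on correlation profiles
#'
#' Each genotype is represented by its row of the pedigree correlation
#' matrix (its correlation profile against all genotypes) and the rows are
#' partitioned into `k` hard clusters by K-means, minimizing inertia (the
#' within-cluster sum of squares) over `n_init` restarts. `k = 20` is the
#' recommended default for real-scale trial pedigrees; for the small
#' synthetic trials use the known family count.
#'
#' @param C Correlation (or relationship) matrix with genotype dimnames.
#' @param k Number of clusters, `1 <= k <= nrow(C)`.
#' @param seed Integer seed making the restarts reproducible.
#' @param n_init Number of random restarts (best inertia kept).
#' @return An object of class `genotype_clusters`: list with `assignments`
#'   (tibble `genotype_id`, `cluster`), `k`, `inertia`, `n`.
#' @export
cluster_genotypes <- function(C, k = 20, seed = 1, n_init = 10) {
  n <- nrow(C)
  if (k > n) stop("`k` must not exceed the number of genotypes", call. = FALSE)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  ids <- rownames(C)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (k == n) {
    cl <- seq_len(n)
    inertia <- 0
  } else if (k == 1) {
    cl <- rep(1L, n)
    ctr <- colMeans(C)
    inertia <- sum(sweep(C, 2, ctr)^2)
  } else {
    set.seed(seed)
    km <- stats::kmeans(C, centers = k, nstart = n_init, iter.max = 100)
    cl <- km$cluster
    inertia <- km$tot.withinss
  }
  structure(list(
    assignments = tibble::tibble(genotype_id = ids,
                                 cluster = as.integer(cl)),
    k = as.integer(k), inertia = inertia, n = n, seed = seed
  ), class = "genotype_clusters")
}

#' @export
print.genotype_clusters <- function(x, ...) {
  cat("<genotype_clusters> n =", x$n, "| k =", x$k,
      "| inertia =", format(x$inertia, digits = 6), "\n")
  invisible(x)
}

#' Inertia against cluster count, for elbow inspection
#'
#' Runs [cluster_genotypes()] for each candidate `k` and tabulates the
#' best-of-restarts inertia, the curve whose elbow guides the choice of the
#' cluster count.
#'
#' @inheritParams cluster_genotypes
#' @param k_values Integer vector of cluster counts to evaluate.
#' @return A tibble with columns `k` and `inertia`.
#' @export
inertia_curve <- function(C, k_values, seed = 1, n_init = 10) {
  if (any(k_values > nrow(C)))
    stop("all `k_values` must be <= number of genotypes", call. = FALSE)
  purrr::map_dfr(k_values, function(k) {
    cg <- cluster_genotypes(C, k = k, seed = seed, n_init = n_init)
    tibble::tibble(k = as.integer(k), inertia = cg$inertia)
  })
}
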