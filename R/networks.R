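# Peer networks are undirected edge lists; direction enters only through
# row normalization, which yields a generally asymmetric influence matrix.

#' Construct a peer network
#'
#' Low-level constructor validating the invariants shared by all four
#' network kinds: no self-loops, at most one edge per unordered pair, every
#' endpoint in the node list, and unit raw weights for the unweighted kinds
#' (`G`, `H`, `T`).
#'
#' @param kind one of `"P"` (patient-sharing), `"G"` (medical group),
#'   `"H"` (hospital), `"T"` (training).
#' @param nodes character vector of physician ids (isolates included).
#' @param edges data.frame with columns `a`, `b`, `weight`; pairs are
#'   canonicalized to `a < b`.
#' @return an object of class `peer_network`.
#' @export
peer_network <- function(kind, nodes, edges = NULL) {
  kind <- match.arg(kind, c("P", "G", "H", "T"))
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids in node list")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.table::data.table(a = character(), b = character(),
                                    weight = numeric())
  } else {
    edges <- data.table::as.data.table(edges)[, c("a", "b", "weight")]
    edges[, c("a", "b") := list(as.character(a), as.character(b))]
    if (any(edges$a == edges$b))
      stop("self-loop edge: ", edges$a[which(edges$a == edges$b)[1]])
    swap <- edges$a > edges$b
    if (any(swap))
      edges[swap, c("a", "b") := list(b, a)]
    if (anyDuplicated(edges[, c("a", "b")]))
      stop("duplicate edges for the same pair")
    miss <- setdiff(c(edges$a, edges$b), nodes)
    if (length(miss))
      stop("edge endpoint not in node list: ", miss[1])
    if (any(edges$weight <= 0)) stop("edge weights must be positive")
    if (kind != "P" && any(edges$weight != 1))
      stop("networks of kind ", kind, " must have unit weights")
    data.table::setorderv(edges, c("a", "b"))
  }
  structure(list(kind = kind, nodes = nodes, edges = edges[]),
            class = "peer_network")
}

#' @export
print.peer_network <- function(x, ...) {
  cat("<peer_network ", x$kind, "> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Build the patient-sharing network from shared-patient records
#'
#' Pools unique-patient counts across payers for each unordered physician
#' pair and keeps pairs whose pooled count reaches `min_shared`; the pooled
#' count becomes the edge weight. The default `min_shared = 1` retains all
#' sharing pairs and lets the weights discount thin links; larger thresholds
#' reproduce validation cutoffs used in the claims-network literature.
#'
#' @param records data.frame with columns `physician_a`, `physician_b`,
#'   `payer`, `n_unique_patients`.
#' @param nodes full physician id list (isolates kept).
#' @param min_shared minimum pooled shared-patient count for an edge.
#' @return a `peer_network` of kind `"P"`.
#' @export
build_patient_sharing_network <- function(records, nodes, min_shared = 1L) {
  stopifnot(min_shared >= 1)
  r <- data.table::as.data.table(records)
  if (nrow(r)) {
    bad <- which(r$physician_a == r$physician_b)
    if (length(bad))
      stop("malformed shared-patient record (physician_a == physician_b) at row ", bad[1])
    a <- pmin(r$physician_a, r$physician_b)
    b <- pmax(r$physician_a, r$physician_b)
    pooled <- data.table::data.table(a = a, b = b, w = r$n_unique_patients)
    pooled <- pooled[, list(weight = sum(w)), by = c("a", "b")]
    pooled <- pooled[pooled$weight >= min_shared, ]
  } else {
    pooled <- NULL
  }
  peer_network("P", nodes, pooled)
}

#' Build an affiliation network by bipartite co-membership projection
#'
#' Connects two physicians if and only if they share at least one
#' organization of the requested kind. Multiple shared organizations still
#' yield a single unit-weight edge: within-organization peers are treated as
#' having equal influence.
#'
#' @param affiliations data.frame with columns `physician`,
#'   `organization_id`, `organization_kind` (`"group"` / `"hospital"`).
#' @param kind `"G"` (projects group affiliations) or `"H"` (hospitals).
#' @param nodes full physician id list.
#' @return a `peer_network` of the requested kind.
#' @export
build_affiliation_network <- function(affiliations, kind = c("G", "H"), nodes) {
  kind <- match.arg(kind)
  org_kind <- c(G = "group", H = "hospital")[[kind]]
  a <- data.table::as.data.table(affiliations)
  a <- unique(a[a$organization_kind == org_kind, c("physician", "organization_id")])
  edges <- NULL
  if (nrow(a)) {
    j <- merge(a, a, by = "organization_id", allow.cartesian = TRUE,
               suffixes = c("_a", "_b"))
    j <- j[j$physician_a < j$physician_b, ]
    if (nrow(j))
      edges <- unique(data.table::data.table(a = j$physician_a, b = j$physician_b))
    if (!is.null(edges)) edges[, "weight" := 1]
  }
  peer_network(kind, nodes, edges)
}

#' Build the training network from school and residency histories
#'
#' Connects two physicians if they attended the same medical school, or the
#' same residency program, within `year_window` years of each other.
#' Physicians with missing years are excluded from the network (kept as
#' isolates) with a warning.
#'
#' @param physicians roster with columns `id`, `school`, `grad_year`,
#'   `residency`, `residency_year`.
#' @param year_window maximum absolute year difference (default 1).
#' @return a `peer_network` of kind `"T"`.
#' @export
build_training_network <- function(physicians, year_window = 1L) {
  stopifnot(year_window >= 0)
  ph <- data.table::as.data.table(physicians)
  pair_up <- function(inst_col, year_col) {
    t0 <- data.table::data.table(id = ph$id, inst = ph[[inst_col]],
                                 year = ph[[year_col]])
    drop <- is.na(t0$inst) | is.na(t0$year)
    if (any(drop)) {
      warning(sum(drop), " physician(s) missing ", inst_col, "/", year_col,
              " excluded from training network")
      t0 <- t0[!drop, ]
    }
    if (nrow(t0) < 2L) return(NULL)
    j <- merge(t0, t0, by = "inst", allow.cartesian = TRUE,
               suffixes = c("_a", "_b"))
    j <- j[j$id_a < j$id_b & abs(j$year_a - j$year_b) <= year_window, ]
    if (!nrow(j)) return(NULL)
    unique(data.table::data.table(a = j$id_a, b = j$id_b))
  }
  edges <- data.table::rbindlist(list(pair_up("school", "grad_year"),
                                      pair_up("residency", "residency_year")))
  if (nrow(edges)) {
    edges <- unique(edges)
    edges[, "weight" := 1]
  } else edges <- NULL
  peer_network("T", ph$id, edges)
}

#' Row-normalized influence matrix of a peer network
#'
#' Returns the sparse matrix `W` in which row `i` holds the weights
#' physician `i` places on each peer: `W[i, j]` is the raw edge weight
#' divided by the total weight of `i`'s edges (equal shares in the
#' unweighted networks, shared-patient proportions in `P`). Rows of
#' physicians with no peers are all zero; the diagonal is zero. Every row
#' therefore sums to exactly 1 or exactly 0, which makes `W` the natural
#' weight for peer averages and guarantees the convergence of the social
#' multiplier series for attenuation below 1.
#'
#' @param network a `peer_network`.
#' @param nodes optional node ordering (defaults to `network$nodes`); must
#'   contain every edge endpoint.
#' @return a sparse `dgCMatrix` with physician ids as dimnames.
#' @export
row_normalize <- function(network, nodes = NULL) {
  stopifnot(inherits(network, "peer_network"))
  if (is.null(nodes)) nodes <- network$nodes
  nodes <- as.character(nodes)
  e <- network$edges
  n <- length(nodes)
  if (nrow(e) == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n), dimnames = list(nodes, nodes)))
  }
  ia <- match(e$a, nodes); ib <- match(e$b, nodes)
  if (anyNA(ia) || anyNA(ib))
    stop("edge endpoint missing from the requested node ordering")
  W <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia), x = rep(e$weight, 2L),
                            dims = c(n, n), dimnames = list(nodes, nodes))
  rs <- Matrix::rowSums(W)
  scale <- ifelse(rs > 0, 1 / rs, 0)
  W <- Matrix::Diagonal(x = scale) %*% W
  dimnames(W) <- list(nodes, nodes)
  methods::as(W, "CsparseMatrix")
}

#' Per-physician degree
#'
#' Number of distinct peers of each physician in a network (unweighted);
#' zero for isolates.
#'
#' @param network a `peer_network`.
#' @return a named integer vector over `network$nodes`.
#' @export
network_degree <- function(network) {
  stopifnot(inherits(network, "peer_network"))
  deg <- table(factor(c(network$edges$a, network$edges$b),
                      levels = network$nodes))
  stats::setNames(as.integer(deg), network$nodes)
}

#' Pairwise edge overlap between networks
#'
#' For each ordered pair of networks, the fraction of the first network's
#' edges also present in the second. Used to confirm the four networks carry
#' distinct information (observed overlaps in physician cohorts are low,
#' under 20%).
#'
#' @param networks named list of at least two `peer_network` objects.
#' @return a square numeric matrix, rows = source network; `NaN` for a
#'   network with no edges.
#' @export
network_overlap <- function(networks) {
  stopifnot(length(networks) >= 2L)
  keys <- lapply(networks, function(nw) paste(nw$edges$a, nw$edges$b, sep = "|"))
  k <- length(networks)
  out <- matrix(NA_real_, k, k, dimnames = list(names(networks), names(networks)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { out[i, j] <- 1; next }
    out[i, j] <- if (length(keys[[i]]) == 0L) NaN
                 else mean(keys[[i]] %in% keys[[j]])
  }
  out
}

#' Union peer adjacency matrix
#'
#' Symmetric 0/1 sparse matrix marking pairs connected in at least one of
#' the given networks. Used as the dependence structure for the
#' network-aware overidentification test: residuals of connected physicians
#' are cross-correlated under a linear-in-means outcome.
#'
#' @param networks named list of `peer_network` objects.
#' @param nodes node ordering (must cover every endpoint).
#' @return a sparse symmetric 0/1 matrix.
#' @export
union_adjacency <- function(networks, nodes) {
  A <- NULL
  for (k in names(networks)) {
    W <- row_normalize(networks[[k]], nodes = nodes)
    B <- W + Matrix::t(W)
    A <- if (is.null(A)) B else A + B
  }
  A@x[] <- 1
  A
}

#' Write a peer network as a weighted edge-list CSV
#'
#' @param network a `peer_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  data.table::fwrite(network$edges, path)
  invisible(path)
}
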