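#' Min-heap of hyperedges with decrease-key
#'
#' A binary min-heap keyed by nonnegative path-length estimates, with
#' deterministic FIFO tie-breaking: among equal keys, the edge inserted
#' earliest is extracted first. `decrease_key` with a key that is not
#' smaller than the current one is a no-op by contract. This is the
#' priority queue driving the shortest-hyperpath heuristic; the heuristic
#' only ever needs the contract (insert / extract-min / decrease-key), so
#' a binary heap stands in for the asymptotically faster pointer-based
#' heaps without affecting results.
#'
#' @return An environment with functions `insert(id, key)`,
#'   `extract_min()` (returns the id, or `NULL` when empty),
#'   `decrease_key(id, key)`, `contains(id)`, `peek_key(id)`, and
#'   `size()`.
#' @examples
#' h <- edge_heap()
#' h$insert("a", 3); h$insert("b", 1)
#' h$extract_min()  # "b"
#' @export
edge_heap <- function() {
  ids <- character()
  keys <- numeric()
  seqs <- integer()
  pos <- new.env(parent = emptyenv())  # id -> index into the arrays
  counter <- 0L

  less <- function(i, j) {
    keys[[i]] < keys[[j]] || (keys[[i]] == keys[[j]] && seqs[[i]] < seqs[[j]])
  }
  swap <- function(i, j) {
    ids[c(i, j)] <<- ids[c(j, i)]
    keys[c(i, j)] <<- keys[c(j, i)]
    seqs[c(i, j)] <<- seqs[c(j, i)]
    assign(ids[[i]], i, envir = pos)
    assign(ids[[j]], j, envir = pos)
  }
  sift_up <- function(i) {
    while (i > 1L) {
      p <- i %/% 2L
      if (!less(i, p)) break
      swap(i, p)
      i <- p
    }
  }
  sift_down <- function(i) {
    n <- length(ids)
    repeat {
      l <- 2L * i
      r <- l + 1L
      sm <- i
      if (l <= n && less(l, sm)) sm <- l
      if (r <= n && less(r, sm)) sm <- r
      if (sm == i) break
      swap(i, sm)
      i <- sm
    }
  }

  insert <- function(id, key) {
    if (exists(id, envir = pos, inherits = FALSE))
      stop("edge '", id, "' is already on the heap")
    counter <<- counter + 1L
    ids <<- c(ids, id)
    keys <<- c(keys, as.numeric(key))
    seqs <<- c(seqs, counter)
    assign(id, length(ids), envir = pos)
    sift_up(length(ids))
    invisible(id)
  }
  extract_min <- function() {
    n <- length(ids)
    if (n == 0L) return(NULL)
    top <- ids[[1L]]
    swap(1L, n)
    ids <<- ids[-n]
    keys <<- keys[-n]
    seqs <<- seqs[-n]
    rm(list = top, envir = pos)
    if (length(ids) > 0L) sift_down(1L)
    top
  }
  decrease_key <- function(id, key) {
    if (!exists(id, envir = pos, inherits = FALSE))
      stop("edge '", id, "' is not on the heap")
    i <- get(id, envir = pos, inherits = FALSE)
    if (key >= keys[[i]]) return(invisible(FALSE))  # no-op by contract
    keys[[i]] <<- as.numeric(key)
    sift_up(i)
    invisible(TRUE)
  }
  contains <- function(id) exists(id, envir = pos, inherits = FALSE)
  peek_key <- function(id) {
    if (!contains(id)) return(NA_real_)
    keys[[get(id, envir = pos, inherits = FALSE)]]
  }
  size <- function() length(ids)

  env <- environment()
  structure(
    list(insert = insert, extract_min = extract_min,
         decrease_key = decrease_key, contains = contains,
         peek_key = peek_key, size = size),
    class = "edge_heap", env = env)
}
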