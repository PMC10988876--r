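#' Randomization configuration
#'
#' Settings for generating per-center predefined allocation lists in a
#' 1:1 two-arm trial. The default mirrors the trial layout: 60 recruiting
#' centers (general practices), an allocation list of 30 patients per
#' center, and permuted blocks of randomly chosen length 2, 4 or 6.
#'
#' Block sizes must be even so that every complete block contains both
#' arms equally; under permuted block randomization the running imbalance
#' of any list prefix is then bounded by `max(block_sizes) / 2`.
#'
#' A seed is always required: lists are reproducible from
#' `(seed, config)` alone, and the package never hard-codes one (in the
#' trial, setting the seed is the sponsor's responsibility, separate from
#' the statistician's code).
#'
#' @param n_centers number of recruiting centers (default 60).
#' @param list_length allocation list length per center (default 30).
#' @param block_sizes even block lengths sampled uniformly (default
#'   `c(2, 4, 6)`); only used by the PBR scheme.
#' @param scheme `"pbr"` (permuted block randomization) or `"cr"`
#'   (complete randomization, independent fair coins).
#' @param seed integer RNG seed (required).
#' @return An object of class `rand_config`.
#' @export
rand_config <- function(n_centers = 60, list_length = 30,
                        block_sizes = c(2, 4, 6),
                        scheme = c("pbr", "cr"), seed) {
  scheme <- match.arg(scheme)
  n_centers <- assert_count(n_centers, "n_centers", lower = 1)
  list_length <- assert_count(list_length, "list_length", lower = 1)
  if (missing(seed)) stop("`seed` is required; lists must be reproducible",
                          call. = FALSE)
  seed <- assert_count(seed, "seed")
  if (scheme == "pbr") {
    if (!length(block_sizes) || any(block_sizes %% 2 != 0) ||
        any(block_sizes < 2))
      stop("all block sizes must be even (1:1 balance within blocks)",
           call. = FALSE)
    if (list_length < max(block_sizes))
      stop("`list_length` must be at least max(block_sizes)", call. = FALSE)
  }
  structure(
    list(n_centers = n_centers, list_length = list_length,
         block_sizes = as.integer(sort(unique(block_sizes))),
         allocation_ratio = c(1L, 1L), scheme = scheme, seed = seed),
    class = "rand_config"
  )
}

# one permuted-block arm sequence; returns 0/1 codes (1 = TT) of exactly
# `list_length` entries (final partial block truncated, mirroring prefix
# use during recruitment) plus the drawn block sizes
pbr_codes <- function(list_length, block_sizes) {
  n_max <- ceiling(list_length / min(block_sizes))
  sizes <- if (length(block_sizes) == 1L) rep(block_sizes, n_max) else
    sample(block_sizes, n_max, replace = TRUE)
  k <- which(cumsum(sizes) >= list_length)[1L]
  sizes <- sizes[seq_len(k)]
  codes <- unlist(lapply(sizes, function(b) sample(rep(c(1L, 0L), b / 2))),
                  use.names = FALSE)
  list(codes = codes[seq_len(list_length)], blocks = sizes)
}

cr_codes <- function(list_length) {
  as.integer(runif(list_length) < 0.5)
}

new_allocation_list <- function(center_id, codes, blocks, scheme) {
  structure(
    list(center_id = center_id,
         entries = ifelse(codes == 1L, "TT", "ST"),
         codes = codes,
         block_boundaries = if (is.null(blocks)) integer(0) else
           cumsum(blocks),
         scheme = scheme),
    class = "allocation_list"
  )
}

#' @export
print.allocation_list <- function(x, ...) {
  cat(sprintf("Allocation list for center %s (%s, %d entries)\n",
              x$center_id, toupper(x$scheme), length(x$entries)))
  cat(" ", paste(head(x$entries, 30), collapse = " "), "\n")
  invisible(x)
}

#' Generate permuted-block allocation lists
#'
#' For every center, block lengths are drawn uniformly at random from
#' `block_sizes`; each block is a uniformly random permutation of equal
#' numbers of TT (prednisolone) and ST (colchicine); blocks are
#' concatenated and the list truncated to exactly `list_length` entries.
#' Output is fully determined by `(seed, center order)`.
#'
#' Block boundaries are stored on each list but excluded from
#' [allocation_df()] exports unless explicitly unblinded, mirroring
#' concealment of the block structure.
#'
#' @param cfg a [rand_config()] with `scheme = "pbr"`.
#' @return A named list of `allocation_list` objects (one per center),
#'   with the config attached as attribute `config`.
#' @export
#' @examples
#' lists <- generate_pbr_lists(rand_config(n_centers = 2, seed = 11))
#' lists[["C01"]]
generate_pbr_lists <- function(cfg) {
  stopifnot(inherits(cfg, "rand_config"))
  if (cfg$scheme != "pbr") stop("config scheme is not 'pbr'", call. = FALSE)
  ids <- center_ids(cfg$n_centers)
  lists <- with_seed_if(cfg$seed, lapply(ids, function(id) {
    g <- pbr_codes(cfg$list_length, cfg$block_sizes)
    new_allocation_list(id, g$codes, g$blocks, "pbr")
  }))
  names(lists) <- ids
  attr(lists, "config") <- cfg
  lists
}

#' Generate complete-randomization allocation lists
#'
#' Comparator scheme: every entry is independently TT or ST with
#' probability 1/2 (a fair coin), with no balance constraint. Generated
#' per center by default; pass `pooled = TRUE` for a single combined list
#' of length `n_centers * list_length` (the granularity of the original
#' lists is not fixed, so both are available).
#'
#' @param cfg a [rand_config()] with `scheme = "cr"`.
#' @param pooled generate one pooled list instead of per-center lists.
#' @return As [generate_pbr_lists()].
#' @export
generate_cr_lists <- function(cfg, pooled = FALSE) {
  stopifnot(inherits(cfg, "rand_config"))
  if (cfg$scheme != "cr") stop("config scheme is not 'cr'", call. = FALSE)
  if (pooled) {
    lists <- with_seed_if(cfg$seed, list(
      pooled = new_allocation_list(
        "pooled", cr_codes(cfg$n_centers * cfg$list_length), NULL, "cr")))
    attr(lists, "config") <- cfg
    return(lists)
  }
  ids <- center_ids(cfg$n_centers)
  lists <- with_seed_if(cfg$seed, lapply(ids, function(id) {
    new_allocation_list(id, cr_codes(cfg$list_length), NULL, "cr")
  }))
  names(lists) <- ids
  attr(lists, "config") <- cfg
  lists
}

center_ids <- function(n) sprintf("C%02d", seq_len(n))

#' Allocate the k-th recruit of a center
#'
#' Consumes the center's predefined list in order; recruitment may stop
#' mid-block (only the list prefix is ever used).
#'
#' @param list an `allocation_list`.
#' @param k recruit index (1-based).
#' @return `"TT"` or `"ST"`.
#' @export
allocate <- function(list, k) {
  stopifnot(inherits(list, "allocation_list"))
  k <- assert_count(k, "k", lower = 1)
  if (k > length(list$entries))
    stop(sprintf("allocation list exhausted: center %s has %d entries, recruit %d requested",
                 list$center_id, length(list$entries), k), call. = FALSE)
  list$entries[k]
}

#' Allocation lists as a data frame
#'
#' One row per list position with columns `center_id`, `position`, `arm`;
#' block boundaries are concealed unless `unblind = TRUE`, which adds a
#' `block` column (intended for testing only).
#'
#' @param lists output of [generate_pbr_lists()] or [generate_cr_lists()].
#' @param unblind expose the block index per position.
#' @return A data frame.
#' @export
allocation_df <- function(lists, unblind = FALSE) {
  rows <- lapply(lists, function(l) {
    d <- data.frame(center_id = l$center_id,
                    position = seq_along(l$entries),
                    arm = l$entries, stringsAsFactors = FALSE)
    if (unblind) {
      if (length(l$block_boundaries)) {
        d$block <- findInterval(d$position - 1L, l$block_boundaries) + 1L
      } else {
        d$block <- NA_integer_
      }
    }
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Running imbalance of an allocation prefix
#'
#' `|#TT - #ST|` over the first `k` entries for each `k`; under permuted
#' blocks this never exceeds `max(block_sizes) / 2`.
#'
#' @param list an `allocation_list`.
#' @return Integer vector of prefix imbalances.
#' @export
prefix_imbalance <- function(list) {
  stopifnot(inherits(list, "allocation_list"))
  s <- cumsum(2L * list$codes - 1L)
  abs(s)
}
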