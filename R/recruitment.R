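#' Recruitment scenario for the imbalance simulation
#'
#' Describes one cell of the recruiting-center dropout simulation: each
#' center independently fails to recruit ("drops out") with probability
#' `dropout_prob`; surviving centers recruit according to a Poisson law
#' with per-center means `lambdas` — together a zero-inflated Poisson
#' recruit count. Two formulations are supported:
#'
#' * **unrestricted** (`restricted = FALSE`): surviving center `i`
#'   recruits `Poisson(lambda_i)` patients, capped at the allocation-list
#'   length. Neither attainment of the target sample size nor avoidance
#'   of over-recruitment is guaranteed.
#' * **restricted** (`restricted = TRUE`): `total_target` patients are
#'   distributed among surviving centers multinomially with probabilities
#'   proportional to their `lambda_i` (conditional on the total, the
#'   Poisson counts are multinomial), per-center counts capped at the
#'   list length with overflow reallocated among uncapped centers. The
#'   total is conserved exactly whenever surviving capacity suffices;
#'   otherwise the shortfall is flagged.
#'
#' @param lambdas per-center Poisson means (clinical expectation: 4-6
#'   patients per practice over the recruitment period).
#' @param dropout_prob probability that a center recruits nobody.
#' @param restricted use the restricted (multinomial) formulation.
#' @param total_target total recruitment under the restricted
#'   formulation; defaults to `round(sum(lambdas))` (the definition of
#'   the restricted total), but may be set to the trial's required 314.
#' @param n_reps simulation replicates (default 1000).
#' @param imbalance_threshold imbalance exceedance threshold (default 20
#'   patients).
#' @param center_cap per-center recruitment cap = allocation-list length
#'   (default 30); allocation beyond the predefined list is impossible,
#'   so the cap is structural in both formulations.
#' @param seed integer RNG seed.
#' @return An object of class `recruitment_scenario`.
#' @export
recruitment_scenario <- function(lambdas = rep(5, 60), dropout_prob = 0.2,
                                 restricted = FALSE, total_target = NULL,
                                 n_reps = 1000, imbalance_threshold = 20,
                                 center_cap = 30, seed = NULL) {
  if (!is.numeric(lambdas) || !length(lambdas) || any(lambdas <= 0))
    stop("all `lambdas` must be positive", call. = FALSE)
  assert_number(dropout_prob, "dropout_prob", 0, 1)
  n_reps <- assert_count(n_reps, "n_reps", lower = 1)
  imbalance_threshold <- assert_count(imbalance_threshold,
                                      "imbalance_threshold", lower = 0)
  center_cap <- assert_count(center_cap, "center_cap", lower = 1)
  if (is.null(total_target)) total_target <- as.integer(round(sum(lambdas)))
  total_target <- assert_count(total_target, "total_target", lower = 1)
  if (!is.null(seed)) seed <- assert_count(seed, "seed")
  structure(
    list(lambdas = as.numeric(lambdas), dropout_prob = dropout_prob,
         restricted = isTRUE(restricted), total_target = total_target,
         n_reps = n_reps, imbalance_threshold = imbalance_threshold,
         center_cap = center_cap, seed = seed),
    class = "recruitment_scenario"
  )
}

# raw draw functions: consume the current RNG stream (callers seed)
draw_counts_unrestricted_ <- function(lambdas, dropout_prob, cap) {
  n <- length(lambdas)
  surv <- runif(n) >= dropout_prob
  counts <- integer(n)
  if (any(surv))
    counts[surv] <- pmin(rpois(sum(surv), lambdas[surv]), cap)
  counts
}

draw_counts_restricted_ <- function(lambdas, dropout_prob, cap,
                                    total_target) {
  n <- length(lambdas)
  surv <- runif(n) >= dropout_prob
  counts <- integer(n)
  idx <- which(surv)
  if (length(idx)) {
    capacity <- length(idx) * cap
    size <- min(total_target, capacity)
    alloc <- as.vector(rmultinom(1, size, prob = lambdas[idx]))
    # cap centers at the list length, reallocating overflow among those
    # with remaining room (still proportional to lambda)
    repeat {
      excess <- sum(pmax(alloc - cap, 0L))
      alloc <- pmin(alloc, cap)
      if (excess == 0L) break
      room <- alloc < cap
      add <- as.vector(rmultinom(1, excess, prob = lambdas[idx][room]))
      alloc[room] <- alloc[room] + add
    }
    counts[idx] <- as.integer(alloc)
  }
  shortfall <- total_target - sum(counts)
  attr(counts, "shortfall") <- as.integer(shortfall)
  counts
}

#' Draw per-center recruit counts
#'
#' One replicate of the zero-inflated Poisson recruitment process of a
#' [recruitment_scenario()]; dispatches on its `restricted` flag. With a
#' `seed` in the scenario the draw is reproducible; otherwise the current
#' RNG stream is consumed.
#'
#' @param s a [recruitment_scenario()].
#' @return Integer vector of per-center counts; under the restricted
#'   formulation, attribute `shortfall` carries `total_target - sum` (0
#'   whenever surviving capacity sufficed).
#' @export
draw_center_counts <- function(s) {
  stopifnot(inherits(s, "recruitment_scenario"))
  with_seed_if(s$seed, {
    if (s$restricted)
      draw_counts_restricted_(s$lambdas, s$dropout_prob, s$center_cap,
                              s$total_target)
    else
      draw_counts_unrestricted_(s$lambdas, s$dropout_prob, s$center_cap)
  })
}

#' Treatment-arm imbalance after allocating recruits along the lists
#'
#' Consumes the first `counts[i]` entries of each center's allocation
#' list and returns `|n_TT - n_ST|` pooled over centers.
#'
#' @param counts per-center recruit counts.
#' @param lists per-center allocation lists (same length and order).
#' @return Integer absolute imbalance.
#' @export
compute_imbalance <- function(counts, lists) {
  if (length(counts) != length(lists))
    stop("`counts` and `lists` differ in length", call. = FALSE)
  diff <- 0L
  for (i in seq_along(lists)) {
    ci <- counts[i]
    if (ci == 0L) next
    codes <- lists[[i]]$codes
    if (ci > length(codes))
      stop(sprintf("allocation list exhausted: center %s has %d entries, %d recruits requested",
                   lists[[i]]$center_id, length(codes), ci), call. = FALSE)
    diff <- diff + sum(codes[seq_len(ci)]) * 2L - ci
  }
  abs(diff)
}

#' Imbalance simulation over a dropout-by-recruitment grid
#'
#' For every combination of center dropout probability and Poisson
#' recruitment mean, and for each randomization scheme, runs `n_reps`
#' replicates of: draw center dropout and recruit counts (zero-inflated
#' Poisson, unrestricted or restricted), generate fresh per-center
#' allocation lists, allocate each center's recruits along its list
#' prefix, and record the absolute treatment-arm imbalance. Summaries
#' include the exceedance probability `P(imbalance > threshold)` and
#' imbalance quantiles per cell.
#'
#' Each grid cell runs on an independent seeded substream derived from
#' `seed`, so the full grid is reproducible bit-exactly from
#' `(seed, arguments)`.
#'
#' @param dropout_probs center dropout probabilities (default
#'   `seq(0.1, 0.5, by = 0.1)`).
#' @param lambdas Poisson recruitment means (default `c(4, 5, 6)`); under
#'   `lambda_mode = "homogeneous"` each cell applies one value to all
#'   centers, under `"heterogeneous"` every replicate draws per-center
#'   means uniformly from `lambdas` (one grid row, labelled `NA`).
#' @param schemes randomization schemes to compare (subset of
#'   `c("pbr", "cr")`).
#' @param n_centers,list_length,block_sizes randomization layout, as
#'   [rand_config()].
#' @param restricted use the restricted (multinomial) recruitment
#'   formulation; see [recruitment_scenario()].
#' @param total_target restricted total; default `NULL` means
#'   `round(n_centers * lambda)` per cell (the sum of that cell's means).
#' @param n_reps replicates per cell (default 1000).
#' @param threshold imbalance exceedance threshold (default 20).
#' @param seed integer RNG seed (required).
#' @param lambda_mode `"homogeneous"` or `"heterogeneous"`.
#' @param keep_replicates attach the per-replicate results as attribute
#'   `replicates` (tidy data frame).
#' @return A data frame with one row per cell and scheme: `scheme`,
#'   `dropout`, `lambda`, `n_reps`, `p_exceed`, `median_imbalance`,
#'   `q90_imbalance`, `max_imbalance`, `mean_total`, `shortfall_rate`.
#' @export
#' @examples
#' g <- run_imbalance_grid(dropout_probs = 0.2, lambdas = 5,
#'                         n_reps = 50, seed = 7)
#' g$p_exceed
run_imbalance_grid <- function(dropout_probs = seq(0.1, 0.5, by = 0.1),
                               lambdas = c(4, 5, 6),
                               schemes = c("pbr", "cr"),
                               n_centers = 60, list_length = 30,
                               block_sizes = c(2, 4, 6),
                               restricted = FALSE, total_target = NULL,
                               n_reps = 1000, threshold = 20, seed,
                               lambda_mode = c("homogeneous",
                                               "heterogeneous"),
                               keep_replicates = FALSE) {
  lambda_mode <- match.arg(lambda_mode)
  schemes <- match.arg(schemes, c("pbr", "cr"), several.ok = TRUE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  seed <- assert_count(seed, "seed")
  n_reps <- assert_count(n_reps, "n_reps", lower = 1)

  lam_cells <- if (lambda_mode == "homogeneous") as.list(lambdas) else
    list(lambdas)
  grid <- expand.grid(scheme = schemes, dropout = dropout_probs,
                      cell = seq_along(lam_cells),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  rows <- vector("list", nrow(grid))
  reps_out <- if (keep_replicates) vector("list", nrow(grid)) else NULL
  for (g in seq_len(nrow(grid))) {
    scheme <- grid$scheme[g]
    dp <- grid$dropout[g]
    lam <- lam_cells[[grid$cell[g]]]
    cell_seed <- substream_seed(seed, g)
    res <- with_seed_if(cell_seed, {
      imb <- integer(n_reps)
      tot <- integer(n_reps)
      short <- logical(n_reps)
      for (r in seq_len(n_reps)) {
        lamv <- if (length(lam) == 1L) rep(lam, n_centers) else
          sample(lam, n_centers, replace = TRUE)
        counts <- if (restricted) {
          tt <- if (is.null(total_target)) as.integer(round(sum(lamv)))
                else total_target
          draw_counts_restricted_(lamv, dp, list_length, tt)
        } else {
          draw_counts_unrestricted_(lamv, dp, list_length)
        }
        diff <- 0L
        total <- 0L
        for (i in which(counts > 0L)) {
          ci <- counts[i]
          codes <- if (scheme == "pbr")
            pbr_codes(list_length, block_sizes)$codes else
            cr_codes(list_length)
          diff <- diff + sum(codes[seq_len(ci)]) * 2L - ci
          total <- total + ci
        }
        imb[r] <- abs(diff)
        tot[r] <- total
        short[r] <- restricted && attr(counts, "shortfall") > 0L
      }
      list(imb = imb, tot = tot, short = short)
    })
    rows[[g]] <- data.frame(
      scheme = scheme, dropout = dp,
      lambda = if (length(lam) == 1L) lam else NA_real_,
      n_reps = n_reps,
      p_exceed = mean(res$imb > threshold),
      median_imbalance = median(res$imb),
      q90_imbalance = unname(quantile(res$imb, 0.9)),
      max_imbalance = max(res$imb),
      mean_total = mean(res$tot),
      shortfall_rate = mean(res$short),
      stringsAsFactors = FALSE
    )
    if (keep_replicates)
      reps_out[[g]] <- data.frame(
        scheme = scheme, dropout = dp,
        lambda = if (length(lam) == 1L) lam else NA_real_,
        replicate = seq_len(n_reps), imbalance = res$imb,
        total_recruited = res$tot, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "threshold") <- threshold
  attr(out, "restricted") <- restricted
  if (keep_replicates) {
    reps <- do.call(rbind, reps_out)
    rownames(reps) <- NULL
    attr(out, "replicates") <- reps
  }
  out
}
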