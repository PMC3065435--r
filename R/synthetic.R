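#' Specification of a synthetic miRNA-mRNA world with planted modules
#'
#' Describes a sparse binary target map with planted co-targeting blocks and
#' matched expression in which each planted mRNA tracks the mean trajectory
#' of its module's miRNAs through a negative linear coupling, plus Gaussian
#' noise. Defaults mirror a short timecourse screen: 300 mRNAs, 30 miRNAs,
#' 5 non-reference conditions, three modules of 7 miRNAs x 40 mRNAs,
#' near-certain in-module targeting (0.95) over a sparse background (0.02),
#' slopes in (-2, -1) and log2-scale noise sd 0.5. The miRNA module size
#' matches the average miRNA cluster size seen in real timecourse screens;
#' it also keeps a planted cluster statistically detectable — random
#' clusters of only background miRNAs are near-zero profiles and hence
#' tight, so a planted cluster is only callable when drawing one entirely
#' from the background pool is rarer than the test level.
#'
#' @param Y,X,T_conditions numbers of mRNAs, miRNAs and conditions.
#' @param n_modules number of planted modules.
#' @param module_mirna_sizes,module_mrna_sizes integer vectors of length
#'   `n_modules`; totals must fit within `X` and `Y`.
#' @param in_module_target_prob,background_target_prob Bernoulli rates of a
#'   predicted pair inside planted blocks / elsewhere.
#' @param beta_range range the planted (negative) slopes are drawn from.
#' @param noise_sd sd of the Gaussian noise added to planted mRNA rows.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(Y = 300L, X = 30L, T_conditions = 5L,
                           n_modules = 3L,
                           module_mirna_sizes = rep(7L, n_modules),
                           module_mrna_sizes = rep(40L, n_modules),
                           in_module_target_prob = 0.95,
                           background_target_prob = 0.02,
                           beta_range = c(-2, -1), noise_sd = 0.5,
                           seed = 1L) {
  spec <- list(Y = as.integer(Y), X = as.integer(X),
               T_conditions = as.integer(T_conditions),
               n_modules = as.integer(n_modules),
               module_mirna_sizes = as.integer(module_mirna_sizes),
               module_mrna_sizes = as.integer(module_mrna_sizes),
               in_module_target_prob = in_module_target_prob,
               background_target_prob = background_target_prob,
               beta_range = as.numeric(beta_range), noise_sd = noise_sd,
               seed = as.integer(seed))
  if (length(spec$module_mirna_sizes) != spec$n_modules ||
      length(spec$module_mrna_sizes) != spec$n_modules) {
    abort("module size vectors must have length n_modules")
  }
  if (sum(spec$module_mirna_sizes) > spec$X ||
      sum(spec$module_mrna_sizes) > spec$Y) {
    abort("planted module sizes exceed X or Y")
  }
  probs <- c(spec$in_module_target_prob, spec$background_target_prob)
  if (any(probs < 0 | probs > 1)) abort("target probabilities must be in [0, 1]")
  if (spec$noise_sd <= 0) abort("noise_sd must be > 0")
  structure(spec, class = "synthetic_spec")
}

mrna_ids <- function(Y) sprintf("mRNA_%04d", seq_len(Y))
mirna_ids <- function(X) sprintf("miR_%03d", seq_len(X))

#' Generate synthetic data with planted miRNA-mRNA modules
#'
#' Map entries are Bernoulli(`in_module_target_prob`) inside planted blocks
#' and Bernoulli(`background_target_prob`) elsewhere. miRNA trajectories
#' are i.i.d. standard Gaussian; each planted mRNA follows
#' `u = alpha + beta * vbar + noise`, where `vbar` is its module's mean
#' miRNA trajectory, `beta` is drawn from `beta_range` and the intercept
#' from N(0, 0.5); background mRNAs are independent Gaussian.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `synthetic_truth`: the `map`, `mirna_expr`,
#'   `mrna_expr` matrices, a `modules` tibble (module, member ids), and a
#'   `pair_beta` tibble of the true planted slopes.
#' @export
simulate_modules <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    rids <- mrna_ids(spec$Y)
    cids <- mirna_ids(spec$X)
    vals <- matrix(
      stats::rbinom(spec$Y * spec$X, 1L, spec$background_target_prob),
      spec$Y, spec$X, dimnames = list(rids, cids))
    mir_blocks <- split_block(spec$module_mirna_sizes)
    mrna_blocks <- split_block(spec$module_mrna_sizes)
    for (k in seq_len(spec$n_modules)) {
      nb <- length(mrna_blocks[[k]]) * length(mir_blocks[[k]])
      vals[mrna_blocks[[k]], mir_blocks[[k]]] <-
        stats::rbinom(nb, 1L, spec$in_module_target_prob)
    }
    map <- map_matrix(vals)

    V <- matrix(stats::rnorm(spec$X * spec$T_conditions), spec$X,
                dimnames = list(cids, cond_ids(spec$T_conditions)))
    U <- matrix(stats::rnorm(spec$Y * spec$T_conditions), spec$Y,
                dimnames = list(rids, cond_ids(spec$T_conditions)))
    beta_tab <- NULL
    for (k in seq_len(spec$n_modules)) {
      vbar <- colMeans(V[mir_blocks[[k]], , drop = FALSE])
      for (j in mrna_blocks[[k]]) {
        beta <- stats::runif(1L, spec$beta_range[1L], spec$beta_range[2L])
        alpha <- stats::rnorm(1L, 0, 0.5)
        U[j, ] <- alpha + beta * vbar +
          stats::rnorm(spec$T_conditions, 0, spec$noise_sd)
        beta_tab <- rbind(beta_tab,
                          data.frame(module = k, mrna_id = rids[j],
                                     true_beta = beta))
      }
    }
    modules <- tibble::tibble(
      module = seq_len(spec$n_modules),
      mirna_ids = purrr::map(mir_blocks, ~cids[.x]),
      mrna_ids = purrr::map(mrna_blocks, ~rids[.x])
    )
    structure(
      list(spec = spec, map = map,
           mirna_expr = expression_matrix(V),
           mrna_expr = expression_matrix(U),
           modules = modules,
           pair_beta = tibble::as_tibble(beta_tab)),
      class = "synthetic_truth"
    )
  })
}

#' Generate pure-null synthetic data for calibration
#'
#' An i.i.d. Bernoulli map and fully independent Gaussian expression on
#' both sides; the truth contains zero planted modules. Used to check that
#' the enrichment and module bootstrap tests reject at their nominal rate.
#'
#' @inheritParams synthetic_spec
#' @param target_prob Bernoulli rate of the map entries.
#' @return a `synthetic_truth` with an empty `modules` table.
#' @export
simulate_null <- function(Y = 300L, X = 30L, T_conditions = 5L,
                          target_prob = 0.1, seed = 1L) {
  withr::with_seed(seed, {
    rids <- mrna_ids(Y)
    cids <- mirna_ids(X)
    map <- map_matrix(matrix(stats::rbinom(Y * X, 1L, target_prob), Y, X,
                             dimnames = list(rids, cids)))
    V <- expression_matrix(matrix(stats::rnorm(X * T_conditions), X,
                                  dimnames = list(cids, cond_ids(T_conditions))))
    U <- expression_matrix(matrix(stats::rnorm(Y * T_conditions), Y,
                                  dimnames = list(rids, cond_ids(T_conditions))))
    structure(
      list(spec = list(Y = Y, X = X, T_conditions = T_conditions,
                       target_prob = target_prob, seed = seed),
           map = map, mirna_expr = V, mrna_expr = U,
           modules = tibble::tibble(module = integer(),
                                    mirna_ids = list(), mrna_ids = list()),
           pair_beta = tibble::tibble(module = integer(),
                                      mrna_id = character(),
                                      true_beta = numeric())),
      class = "synthetic_truth"
    )
  })
}

split_block <- function(sizes) {
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  purrr::map2(starts, ends, seq)
}

cond_ids <- function(T_n) sprintf("cond_%d", seq_len(T_n))

#' Write a synthetic data set to a directory
#'
#' Writes `map.tsv`, `mirna_expr.tsv`, `mrna_expr.tsv` (labelled TSV) and
#' `truth.json` (planted memberships and slopes).
#'
#' @param truth a `synthetic_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(truth, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(truth$map, file.path(dir, "map.tsv"))
  write_matrix(truth$mirna_expr, file.path(dir, "mirna_expr.tsv"))
  write_matrix(truth$mrna_expr, file.path(dir, "mrna_expr.tsv"))
  jsonlite::write_json(
    list(spec = truth$spec,
         modules = purrr::pmap(truth$modules, function(module, mirna_ids,
                                                       mrna_ids) {
           list(module = module, mirna_ids = mirna_ids, mrna_ids = mrna_ids)
         }),
         pair_beta = truth$pair_beta),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic miRmR data: %d mRNAs x %d miRNAs, %d conditions, %d planted module(s)\n",
    nrow(x$map), ncol(x$map), ncol(x$mrna_expr), nrow(x$modules)))
  invisible(x)
}
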