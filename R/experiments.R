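# Perturbation protocol: single-pathway weight scaling and lesions,
# replicate runs per condition, and joint two-pathway grids.

SWEEP_SCALES <- c(0, 1 / 8, 1 / 4, 1 / 2, 1, 2, 4, 8)

# Output pathways of each population, source first.
POPULATION_OUTPUTS <- list(W = c("WNi", "WRi"),
                           N = c("NRi", "NWi"),
                           R = c("RRe", "RWe"))

#' Enumerate the synaptic-weight sweep conditions
#'
#' Builds the full table of single-pathway alterations: each of the six
#' pathways at scale factors 0 (lesion), 1/8, 1/4, 1/2, 1 (control), 2, 4
#' and 8 of its control weight. Every resolved weight is exactly
#' `control * scale`.
#'
#' @param control control [pathway_weights()].
#' @param scales scale factors; default the standard eight.
#' @return data.frame `pathway, scale, weight` with one row per condition.
#' @examples
#' subset(sweep_table(), pathway == "RRe")
#' @export
sweep_table <- function(control = pathway_weights(), scales = SWEEP_SCALES) {
  validate_weights(control)
  out <- expand.grid(pathway = PATHWAYS, scale = scales,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$weight <- unname(control[out$pathway]) * out$scale
  out[order(match(out$pathway, PATHWAYS), out$scale), , drop = FALSE]
}

#' Run one sweep condition with replicate simulations
#'
#' Scales one pathway's weight, runs `replicates` noisy simulations seeded
#' `base_seed + 0:(replicates-1)`, scores each, and returns one metrics row
#' per replicate tagged with the condition. Seeds are condition-independent,
#' so conditions differ only in the manipulated weight, not in their noise.
#' A failing replicate is recorded as an `NA` row (with a warning) without
#' aborting the sweep.
#'
#' @param pathway one of `"RRe", "RWe", "WNi", "WRi", "NRi", "NWi"`.
#' @param scale scale factor; 0 is a lesion, 1 the control.
#' @param params base [sleep_params()] (control weights).
#' @param replicates number of replicate simulations (default 8).
#' @param base_seed seed of the first replicate.
#' @param ... passed to [run_simulation()] (e.g. `duration`, `store_every`).
#' @return data.frame: condition columns (`pathway`, `scale`, `weight`,
#'   `replicate`, `seed`) followed by the [compute_metrics()] columns.
#' @export
run_condition <- function(pathway, scale, params = sleep_params(),
                          replicates = 8, base_seed = 1, ...) {
  pathway <- match.arg(pathway, PATHWAYS)
  stopifnot(is.finite(scale), scale >= 0, replicates >= 1)
  p <- params
  p$weights[pathway] <- p$weights[[pathway]] * scale
  rows <- lapply(seq_len(replicates) - 1L, function(k) {
    seed <- as.integer(base_seed) + k
    m <- tryCatch({
      ts <- run_simulation(p, seed = seed, ...)
      compute_metrics(build_hypnogram(ts))
    }, error = function(e) {
      warning(sprintf("replicate %d of %s x%g failed: %s",
                      k + 1L, pathway, scale, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(m)) {
      m <- compute_metrics(hypnogram("WAKE", dt = 1))
      m[1, ] <- NA_real_
    }
    cbind(data.frame(pathway = pathway, scale = scale,
                     weight = unname(p$weights[[pathway]]),
                     replicate = k + 1L, seed = seed), m)
  })
  do.call(rbind, rows)
}

#' Run the full single-pathway sweep
#'
#' [run_condition()] over every pathway x scale combination (48 conditions
#' under the defaults, including the six lesions and the shared control
#' scale).
#'
#' @param params base [sleep_params()].
#' @param pathways,scales conditions to cover.
#' @param replicates,base_seed,... as in [run_condition()].
#' @return Long data.frame of per-replicate metrics rows.
#' @export
run_sweep <- function(params = sleep_params(), pathways = PATHWAYS,
                      scales = SWEEP_SCALES, replicates = 8,
                      base_seed = 1, ...) {
  grid <- expand.grid(pathway = pathways, scale = scales,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    run_condition(grid$pathway[i], grid$scale[i], params,
                  replicates = replicates, base_seed = base_seed, ...)
  }))
}

#' Joint two-pathway manipulation grid
#'
#' Scales both output pathways of one population over a grid of scale-factor
#' pairs and reports the mean percentage of time in each vigilance state per
#' cell (averaged over replicates).
#'
#' @param population `"W"`, `"N"` or `"R"`; its two output pathways are
#'   manipulated (W: WNi and WRi; N: NRi and NWi; R: RRe and RWe).
#' @param params base [sleep_params()].
#' @param scales_a,scales_b scale grids for the first and second output
#'   pathway.
#' @param replicates,base_seed,... as in [run_condition()].
#' @return data.frame `pathway_a, scale_a, pathway_b, scale_b, pct_WAKE,
#'   pct_NREM, pct_REM` (one row per grid cell; the three percentages sum to
#'   100).
#' @export
run_joint_sweep <- function(population, params = sleep_params(),
                            scales_a = SWEEP_SCALES, scales_b = SWEEP_SCALES,
                            replicates = 8, base_seed = 1, ...) {
  population <- match.arg(population, names(POPULATION_OUTPUTS))
  pws <- POPULATION_OUTPUTS[[population]]
  grid <- expand.grid(scale_a = scales_a, scale_b = scales_b,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$weights[pws[1]] <- p$weights[[pws[1]]] * grid$scale_a[i]
    p$weights[pws[2]] <- p$weights[[pws[2]]] * grid$scale_b[i]
    pct <- vapply(seq_len(replicates) - 1L, function(k) {
      ts <- run_simulation(p, seed = as.integer(base_seed) + k, ...)
      m <- compute_metrics(build_hypnogram(ts))
      c(m$pct_WAKE, m$pct_NREM, m$pct_REM)
    }, numeric(3))
    mean_pct <- rowMeans(pct)
    data.frame(pathway_a = pws[1], scale_a = grid$scale_a[i],
               pathway_b = pws[2], scale_b = grid$scale_b[i],
               pct_WAKE = mean_pct[1], pct_NREM = mean_pct[2],
               pct_REM = mean_pct[3])
  })
  do.call(rbind, rows)
}
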