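#' Assemble a run configuration
#'
#' Bundles every stage's parameters plus the refinement criterion into
#' one object; \code{\link{read_run_config}} fills the same structure
#' from a YAML file.
#'
#' @param skfcm,rough,seeds,growcut Parameter objects for the stages.
#' @param post_radius Disk radius of the final closing, default 1.
#' @param refine_threshold Relative area-change threshold of the
#'   refinement criterion, default 0.10.
#' @param min_solidity Solidity floor of the refinement criterion,
#'   default 0.85.
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(skfcm = skfcm_params(), rough = rough_params(),
                       seeds = seed_params(), growcut = growcut_params(),
                       post_radius = 1L, refine_threshold = 0.10,
                       min_solidity = 0.85) {
  structure(list(skfcm = skfcm, rough = rough, seeds = seeds,
                 growcut = growcut, post_radius = as.integer(post_radius),
                 refine_threshold = refine_threshold,
                 min_solidity = min_solidity),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized blocks: \code{skfcm}, \code{rough}, \code{seeds},
#' \code{growcut}, \code{post} (key \code{radius}) and \code{refine}
#' (keys \code{threshold}, \code{min_solidity}). Unknown blocks or keys
#' are rejected, not ignored.
#'
#' @param path YAML file.
#' @return A \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("skfcm", "rough", "seeds", "growcut", "post", "refine")
  extra <- setdiff(names(y), known)
  if (length(extra) > 0L)
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  apply_block <- function(ctor, block) {
    args <- y[[block]]
    if (is.null(args)) return(ctor())
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad) > 0L)
      stop(sprintf("unknown keys in '%s': %s", block,
                   paste(bad, collapse = ", ")), call. = FALSE)
    do.call(ctor, args)
  }
  post <- y$post
  if (!is.null(post) && length(setdiff(names(post), "radius")) > 0L)
    stop("unknown keys in 'post'", call. = FALSE)
  refine <- y$refine
  if (!is.null(refine) &&
      length(setdiff(names(refine), c("threshold", "min_solidity"))) > 0L)
    stop("unknown keys in 'refine'", call. = FALSE)
  run_config(skfcm = apply_block(skfcm_params, "skfcm"),
             rough = apply_block(rough_params, "rough"),
             seeds = apply_block(seed_params, "seeds"),
             growcut = apply_block(growcut_params, "growcut"),
             post_radius = if (is.null(post$radius)) 1L else post$radius,
             refine_threshold = if (is.null(refine$threshold)) 0.10
                                else refine$threshold,
             min_solidity = if (is.null(refine$min_solidity)) 0.85
                            else refine$min_solidity)
}

#' Run the full coarse-to-fine pipeline
#'
#' Rough-segments the whole sequence from one manual bounding box, flags
#' slices whose mask changes abruptly relative to their toward-seed
#' neighbor (or loses solidity), refines each flagged slice with
#' automatically seeded GrowCut using the nearest unflagged slice
#' (searching toward the seed slice first) as template, and applies the
#' final morphological closing. The single manual input is
#' \code{start_bbox}; no further interaction is consumed.
#'
#' @param volume A \code{\link{ct_volume}}.
#' @param start_index Slice carrying the manual box (largest kidney
#'   contour).
#' @param start_bbox Manual \code{\link{bbox}}.
#' @param config A \code{\link{run_config}}.
#' @return List of class \code{"pipeline_run"}: \code{masks} (final,
#'   full-slice, named by slice index), \code{rough_masks}, \code{report}
#'   (per-slice data frame: flagged, refined, failed, convergence,
#'   template used, crop box), \code{n_interactions} (always 1: the
#'   initial box).
#' @export
run_pipeline <- function(volume, start_index, start_bbox,
                         config = run_config()) {
  rough_res <- rough_segment_sequence(volume, start_index, start_bbox,
                                      config$skfcm, config$rough)
  idx <- as.integer(names(rough_res))

  # Slices are processed outward from the seed slice. Each slice's rough
  # mask is compared against the final (refined or rough) mask of its
  # adjacent toward-seed neighbor -- flagged when the area jumps, the
  # solidity drops, or the rough stage failed outright -- and a flagged
  # slice is refined against that same neighbor mask, so the template is
  # always both adjacent and already accepted. The seed slice is never
  # flagged.
  masks <- list()
  flagged <- stats::setNames(logical(length(idx)), names(rough_res))
  refined <- stats::setNames(logical(length(idx)), names(rough_res))
  template_of <- stats::setNames(rep(NA_integer_, length(idx)), names(rough_res))
  iterations <- stats::setNames(rep(NA_integer_, length(idx)), names(rough_res))
  process <- function(i) {
    key <- as.character(i)
    r <- rough_res[[key]]
    t_i <- if (i > start_index) i - 1L else i + 1L
    tmpl <- if (i == start_index) NULL else masks[[as.character(t_i)]]
    if (i == start_index) {
      flagged[key] <<- FALSE
    } else if (r$failed || is.null(tmpl) || sum(tmpl) == 0L) {
      flagged[key] <<- TRUE
    } else {
      flagged[key] <<- needs_refinement(tmpl, r$mask,
                                        config$refine_threshold,
                                        config$min_solidity)
    }
    if (!flagged[key]) {
      masks[[key]] <<- r$mask
      return(invisible())
    }
    if (is.null(tmpl) || sum(tmpl) == 0L) {
      warning(sprintf("slice %d: no usable template; keeping rough mask", i),
              call. = FALSE)
      masks[[key]] <<- r$mask
      return(invisible())
    }
    m <- tryCatch(
      refine_slice(volume$slices[[i]], tmpl, config$seeds, config$growcut,
                   margin = config$rough$margin),
      error = function(e) {
        warning(sprintf("slice %d: refinement failed (%s); keeping rough mask",
                        i, conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(m)) {
      masks[[key]] <<- r$mask
      return(invisible())
    }
    masks[[key]] <<- m
    refined[key] <<- TRUE
    template_of[key] <<- t_i
    iterations[key] <<- attr(m, "iterations")
    invisible()
  }
  process(start_index)
  for (i in idx[idx > start_index]) process(i)     # up-stack, outward
  for (i in rev(idx[idx < start_index])) process(i) # down-stack, outward

  final <- lapply(masks, postprocess_mask, radius = config$post_radius)
  report <- data.frame(
    slice = idx,
    failed = vapply(rough_res, function(r) r$failed, logical(1)),
    skfcm_converged = vapply(rough_res, function(r) r$converged, logical(1)),
    flagged = as.logical(flagged),
    refined = refined,
    template = template_of,
    growcut_iterations = iterations,
    row_lo = vapply(rough_res, function(r) r$bbox[["row_lo"]], integer(1)),
    col_lo = vapply(rough_res, function(r) r$bbox[["col_lo"]], integer(1)),
    row_hi = vapply(rough_res, function(r) r$bbox[["row_hi"]], integer(1)),
    col_hi = vapply(rough_res, function(r) r$bbox[["col_hi"]], integer(1)),
    row.names = NULL)
  structure(list(masks = final, rough_masks = lapply(rough_res, `[[`, "mask"),
                 report = report, n_interactions = 1L),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run: %d slices, %d flagged, %d refined, %d failed>\n",
              nrow(x$report), sum(x$report$flagged), sum(x$report$refined),
              sum(x$report$failed)))
  invisible(x)
}

#' Write a pipeline run to disk
#'
#' @param run A \code{\link{run_pipeline}} result.
#' @param dir Output directory; masks go to \code{dir/masks} as a PNG
#'   stack, the report to \code{dir/report.json}.
#' @return Invisibly, \code{dir}.
#' @export
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ord <- order(as.integer(names(run$masks)))
  write_mask_stack(unname(run$masks[ord]), file.path(dir, "masks"), "png_stack")
  jsonlite::write_json(
    list(report = run$report, n_interactions = run$n_interactions),
    file.path(dir, "report.json"), dataframe = "rows", auto_unbox = TRUE,
    pretty = TRUE, na = "null")
  invisible(dir)
}
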