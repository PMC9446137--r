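#' Session scripts
#'
#' A session script is an ordered list of actions — the headless
#' counterpart of the interactive workflow.  Scripts serialize to a JSON
#' array with one object per action:
#'
#' ```
#' [
#'   {"op": "set_gamma", "gamma": 0.8},
#'   {"op": "set_region", "top": 0, "left": 0, "bottom": 64, "right": 64},
#'   {"op": "propose", "algorithm": "slic", "n_segments": 30, "compactness": 10},
#'   {"op": "select", "proposal": 0, "segment": 12, "class": "granulation"},
#'   {"op": "brush", "row": 10, "col": 12, "radius": 3, "class": "slough"},
#'   {"op": "wand", "row": 40, "col": 41, "tolerance": 0.1, "class": "background"},
#'   {"op": "save", "stem": "out/sample01", "allow_unlabeled": false}
#' ]
#' ```
#'
#' `proposal` and `segment` indices are 0-based; `class` is a palette id
#' or name.  Replay on the same image and palette is deterministic down to
#' the bytes of the written label PNG.
#'
#' @param path path to a JSON script file.
#' @return a list of action lists.
#' @export
read_session_script <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  script <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.list(script)) stop("script must be a JSON array of actions",
                             call. = FALSE)
  script
}

#' @rdname read_session_script
#' @param script a list of action lists.
#' @export
write_session_script <- function(script, path) {
  jsonlite::write_json(script, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

param_fields <- list(
  felzenszwalb = c("scale_k", "sigma", "min_size"),
  slic = c("n_segments", "compactness", "max_iter", "enforce_connectivity"),
  quickshift = c("kernel_size", "max_dist", "ratio"),
  kmeans = c("n_clusters", "max_iter", "n_init", "seed"))

params_from_action <- function(algorithm, action) {
  ctor <- switch(algorithm, felzenszwalb = felz_params, slic = slic_params,
                 quickshift = quickshift_params, kmeans = kmeans_params)
  given <- action[intersect(param_fields[[algorithm]], names(action))]
  do.call(ctor, given)
}

#' Replay a session script
#'
#' Executes the actions of a script sequentially on a fresh session for
#' the given image.  The first invalid action aborts with an error naming
#' its (1-based) position; nothing is written in that case beyond files
#' already saved by earlier `save` actions.
#'
#' @param img a `raster_image`.
#' @param script a list of actions, or the path of a JSON script file
#'   (see [read_session_script()]).
#' @param palette a [tissue_palette()].
#' @return a list with `mask` (the final `label_map`), `files` (paths
#'   written by `save` actions) and `session` (the finished session).
#' @export
run_script <- function(img, script, palette = default_palette()) {
  if (is.character(script) && length(script) == 1L)
    script <- read_session_script(script)
  session <- new_session(img, palette)
  files <- character(0)
  for (i in seq_along(script)) {
    action <- script[[i]]
    res <- tryCatch(apply_action(session, action),
                    error = function(e) e)
    if (inherits(res, "error"))
      stop(sprintf("script action %d (op '%s') failed: %s", i,
                   if (is.null(action$op)) "?" else action$op,
                   conditionMessage(res)), call. = FALSE)
    if (is.character(res)) files <- c(files, res)
  }
  list(mask = session$mask, files = files, session = session)
}

apply_action <- function(session, action) {
  op <- action$op
  if (is.null(op)) stop("action has no 'op' field")
  switch(op,
    set_gamma = {
      set_gamma(session, action$gamma)
      invisible(NULL)
    },
    set_region = {
      region <- if (is.null(action$top)) NULL
                else rect(action$top, action$left, action$bottom, action$right)
      set_region(session, region)
      invisible(NULL)
    },
    propose = {
      propose(session, action$algorithm,
              params_from_action(action$algorithm, action))
      invisible(NULL)
    },
    select = {
      select_segment(session, action$proposal + 1L, action$segment,
                     script_class(action$class))
      invisible(NULL)
    },
    brush = {
      brush(session, c(action$row, action$col), action$radius,
            script_class(action$class))
      invisible(NULL)
    },
    wand = {
      magic_wand(session, c(action$row, action$col), action$tolerance,
                 script_class(action$class))
      invisible(NULL)
    },
    save = {
      allow <- isTRUE(action$allow_unlabeled)
      save_pair(session, action$stem, allow_unlabeled = allow)
    },
    stop("unknown op: ", op)
  )
}

script_class <- function(x) {
  if (is.null(x)) stop("action has no 'class' field")
  x
}
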