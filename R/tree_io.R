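TREE_FORMAT_VERSION <- "1.0"

#' Save and load technology trees as JSON
#'
#' The on-disk dialect is a single JSON object with fields
#' `format_version`, `metadata` (generation seed, parameters and the basic
#' log ids), `items` (array of `{id, kind, name}`), `recipes` (array of
#' `{output, inputs}` with inputs in canonical sorted order) and
#' `log_values` (object mapping log id to points, present only when values
#' have been assigned).  `load_tree(save_tree(tree, path))` reproduces the
#' tree exactly, metadata included.
#'
#' @param tree A `techtree`.
#' @param path File path.
#' @param log_values Optional named value vector to embed (defaults to
#'   `tree$log_values`).
#' @return `save_tree()`: `path`, invisibly.  `load_tree()`: a `techtree`.
#' @export
save_tree <- function(tree, path, log_values = tree$log_values) {
  stopifnot(inherits(tree, "techtree"))
  obj <- list(
    format_version = TREE_FORMAT_VERSION,
    metadata = list(
      seed = tree$params$seed,
      params = unclass(tree$params)[setdiff(names(tree$params), "seed")],
      basic_logs = as.list(tree$basic_log_ids)
    ),
    items = lapply(seq_len(nrow(tree$items)), function(i) {
      list(id = tree$items$id[i], kind = tree$items$kind[i],
           name = tree$items$name[i])
    }),
    recipes = lapply(names(tree$recipes), function(out) {
      list(output = out, inputs = as.list(tree$recipes[[out]]))
    })
  )
  if (!is.null(log_values)) obj$log_values <- as.list(log_values)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_tree
#' @export
load_tree <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stopf("cannot parse tree file: %s",
                                            conditionMessage(e)))
  if (is.null(obj$format_version)) {
    stopf("tree file schema error: missing 'format_version'")
  }
  if (!identical(obj$format_version, TREE_FORMAT_VERSION)) {
    stopf("unsupported tree format version '%s' (expected '%s')",
          obj$format_version, TREE_FORMAT_VERSION)
  }
  for (f in c("items", "recipes")) {
    if (is.null(obj[[f]])) stopf("tree file schema error: missing '%s'", f)
  }
  items <- data.frame(
    id = vapply(obj$items, function(x) as.character(x$id), character(1)),
    kind = vapply(obj$items, function(x) as.character(x$kind), character(1)),
    name = vapply(obj$items, function(x)
      as.character(x$name %||% x$id), character(1)),
    stringsAsFactors = FALSE)
  recipes <- stats::setNames(
    lapply(obj$recipes, function(r) {
      sort(vapply(r$inputs, as.character, character(1)))
    }),
    vapply(obj$recipes, function(r) as.character(r$output), character(1)))
  md <- obj$metadata
  params <- NULL
  if (!is.null(md$params)) {
    params <- do.call(tree_gen_params,
                      c(md$params, list(seed = md$seed)))
  }
  log_values <- NULL
  if (!is.null(obj$log_values)) {
    log_values <- vapply(obj$log_values, as.numeric, numeric(1))
  }
  new_techtree(items, recipes,
               base_ids = items$id[items$kind == "base"],
               basic_log_ids = vapply(md$basic_logs %||% list(),
                                      as.character, character(1)),
               params = params, log_values = log_values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
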