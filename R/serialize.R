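#' Serialize a treatment-effect tree to JSON
#'
#' Writes a versioned JSON document holding the nested node structure
#' (split nodes with feature index, name and threshold; leaves with effect
#' estimate and arm counts), the splitting criterion, epsilon parameters
#' and the full configuration snapshot, so the identical model can be
#' reloaded — or regrown from the same data — later. The split direction
#' convention ("value at or below the threshold goes left") is recorded in
#' the document. Serialization is deterministic: the same fitted model
#' always produces byte-identical output.
#'
#' @param model a fitted `"hettree"`.
#' @param path file path; if `NULL` the JSON string is returned instead.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @seealso [read_hettree()]
#' @export
write_hettree <- function(model, path = NULL) {
  stopifnot(inherits(model, "hettree"))
  node_doc <- function(id) {
    nd <- model$nodes[[id]]
    if (nd$leaf) {
      list(type = "leaf", tau = nd$tau, n = nd$n,
           n_treated = nd$n_treated, n_control = nd$n_control)
    } else {
      list(type = "split", feature = nd$feature,
           feature_name = model$feature_names[nd$feature],
           threshold = nd$threshold, fit = nd$fit, hete = nd$hete,
           archive_size = nd$archive_size,
           left = node_doc(nd$left), right = node_doc(nd$right))
    }
  }
  doc <- list(format = "hettree", version = 1L,
              direction = "left: value <= threshold",
              criterion = model$criterion, eps = model$eps,
              select_rule = model$select_rule, config = model$config,
              feature_names = as.list(model$feature_names),
              n = model$n, n_splits = model$n_splits,
              root = node_doc(model$root))
  # I(17) significant digits: doubles survive the round-trip exactly
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE, null = "null", na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a serialized treatment-effect tree
#'
#' Parses a document written by [write_hettree()] and rebuilds the fitted
#' model. Malformed documents (wrong format tag, unsupported version,
#' missing children or fields) are rejected with an explicit error.
#'
#' @param path file path, or a JSON string.
#' @return An object of class `"hettree"` that predicts identically to the
#'   model that was serialized.
#' @export
read_hettree <- function(path) {
  txt <- if (length(path) == 1L && file.exists(path))
    paste(readLines(path, warn = FALSE), collapse = "\n") else path
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e)
                    stop("not a valid hettree document: ",
                         conditionMessage(e)))
  if (!identical(doc$format, "hettree"))
    stop("not a hettree document (missing format tag)")
  if (!identical(as.integer(doc$version), 1L))
    stop("unsupported hettree document version: ", doc$version)
  for (f in c("criterion", "eps", "config", "feature_names", "root"))
    if (is.null(doc[[f]])) stop("malformed hettree document: missing ", f)
  nodes <- list()
  build <- function(d) {
    if (is.null(d$type)) stop("malformed hettree document: node lacks type")
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, leaf = TRUE, tau = NA_real_, n = 0L,
                         n_treated = 0L, n_control = 0L,
                         feature = NA_integer_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_,
                         fit = NA_real_, hete = NA_real_,
                         archive_size = NA_integer_)
    if (identical(d$type, "leaf")) {
      if (is.null(d$tau)) stop("malformed hettree document: leaf lacks tau")
      nodes[[id]]$tau <<- as.numeric(d$tau)
      nodes[[id]]$n <<- as.integer(d$n)
      nodes[[id]]$n_treated <<- as.integer(d$n_treated)
      nodes[[id]]$n_control <<- as.integer(d$n_control)
    } else if (identical(d$type, "split")) {
      if (is.null(d$left) || is.null(d$right))
        stop("malformed hettree document: split node lacks a child")
      if (is.null(d$feature) || is.null(d$threshold))
        stop("malformed hettree document: split node lacks feature/threshold")
      nodes[[id]]$leaf <<- FALSE
      nodes[[id]]$feature <<- as.integer(d$feature)
      nodes[[id]]$threshold <<- as.numeric(d$threshold)
      nodes[[id]]$fit <<- if (is.null(d$fit)) NA_real_
                          else as.numeric(d$fit)
      nodes[[id]]$hete <<- if (is.null(d$hete)) NA_real_
                           else as.numeric(d$hete)
      nodes[[id]]$archive_size <<- if (is.null(d$archive_size))
        NA_integer_ else as.integer(d$archive_size)
      nodes[[id]]$left <<- build(d$left)
      nodes[[id]]$right <<- build(d$right)
    } else stop("malformed hettree document: unknown node type ", d$type)
    id
  }
  root <- build(doc$root)
  cfg <- doc$config
  cfg$seed <- if (is.null(cfg$seed)) NA_integer_ else as.integer(cfg$seed)
  structure(list(nodes = nodes, root = root,
                 n_splits = as.integer(doc$n_splits),
                 criterion = doc$criterion,
                 eps = as.numeric(unlist(doc$eps)),
                 select_rule = doc$select_rule, config = cfg,
                 feature_names = as.character(unlist(doc$feature_names)),
                 n = as.integer(doc$n), call = NULL),
            class = "hettree")
}
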