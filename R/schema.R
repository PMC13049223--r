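#' Anatomical label schemas for the bronchial tree
#'
#' A label schema names the branches of a bronchial tree and fixes their
#' parent-child relations, rooted at the trachea. Two schemas ship with the
#' package: `"human"` covers the trachea down to the segmental bronchi
#' (B1-B10 on both sides, with the right intermediate bronchus and the
#' lingula as intermediate levels), and `"porcine"` covers the pig airway
#' (cranial/caudal subdivisions of the upper-lobe bronchi, an accessory
#' lobe on the right).
#'
#' @param schema_id `"human"`, `"porcine"`, or a custom id when `labels`
#'   and `parent_of` are supplied.
#' @param labels Character vector of branch names (custom schemas only).
#' @param parent_of Named character vector mapping each non-root label to its
#'   parent label (custom schemas only). Must describe a tree rooted at
#'   `"trachea"`.
#' @return An object of class `label_schema`: a list with `schema_id`,
#'   `labels` and `parent_of`.
#' @examples
#' sch <- label_schema("human")
#' schema_parent(sch, "RUL B1")
#' @export
label_schema <- function(schema_id = c("human", "porcine"), labels = NULL,
                         parent_of = NULL) {
  if (!is.null(labels) || !is.null(parent_of)) {
    stopifnot(is.character(schema_id), length(schema_id) == 1L,
              is.character(labels), !anyDuplicated(labels),
              is.character(parent_of), !is.null(names(parent_of)))
    sch <- structure(list(schema_id = schema_id, labels = labels,
                          parent_of = parent_of),
                     class = "label_schema")
    validate_schema(sch)
    return(sch)
  }
  schema_id <- match.arg(schema_id)
  parent_of <- switch(schema_id, human = .human_parents(),
                      porcine = .porcine_parents())
  sch <- structure(list(schema_id = schema_id,
                        labels = c("trachea", names(parent_of)),
                        parent_of = parent_of),
                   class = "label_schema")
  validate_schema(sch)
  sch
}

.human_parents <- function() {
  c("RMB" = "trachea",
    "RUL" = "RMB", "RUL B1" = "RUL", "RUL B2" = "RUL", "RUL B3" = "RUL",
    "RIB" = "RMB",
    "RML" = "RIB", "RML B4" = "RML", "RML B5" = "RML",
    "RLL" = "RIB", "RLL B6" = "RLL", "RLL B7" = "RLL", "RLL B8" = "RLL",
    "RLL B9" = "RLL", "RLL B10" = "RLL",
    "LMB" = "trachea",
    "LUL" = "LMB", "LUL B1/2" = "LUL", "LUL B3" = "LUL",
    "lingula" = "LUL", "LUL B4" = "lingula", "LUL B5" = "lingula",
    "LLL" = "LMB", "LLL B6" = "LLL", "LLL B7/8" = "LLL",
    "LLL B9" = "LLL", "LLL B10" = "LLL")
}

.porcine_parents <- function() {
  c("RMB" = "trachea",
    "RB1" = "RMB", "RB1Cr" = "RB1", "RB1Cd" = "RB1",
    "RB2" = "RMB", "RB3" = "RMB", "RB4" = "RMB", "RB5" = "RMB",
    "LMB" = "trachea",
    "LB1" = "LMB", "LB1Cr" = "LB1", "LB1Cd" = "LB1",
    "LB2" = "LMB", "LB3" = "LMB")
}

validate_schema <- function(schema) {
  stopifnot(inherits(schema, "label_schema"))
  po <- schema$parent_of
  if (!all(names(po) %in% schema$labels) || !all(po %in% schema$labels))
    stop("schema parent map refers to unknown labels", call. = FALSE)
  if ("trachea" %in% names(po))
    stop("'trachea' must be the schema root and have no parent", call. = FALSE)
  # every label must reach the trachea without cycles
  for (lab in setdiff(schema$labels, "trachea")) {
    seen <- character()
    cur <- lab
    while (cur != "trachea") {
      if (cur %in% seen) stop("cycle in schema at '", lab, "'", call. = FALSE)
      seen <- c(seen, cur)
      if (!cur %in% names(po))
        stop("label '", cur, "' has no parent and is not the root",
             call. = FALSE)
      cur <- po[[cur]]
    }
  }
  invisible(schema)
}

#' @rdname label_schema
#' @param schema A `label_schema`.
#' @param label A branch label present in the schema.
#' @return `schema_parent()`: the parent label, or `NA` for the root.
#' @export
schema_parent <- function(schema, label) {
  stopifnot(inherits(schema, "label_schema"))
  if (identical(label, "trachea")) return(NA_character_)
  if (!label %in% schema$labels)
    stop("label '", label, "' not in schema '", schema$schema_id, "'",
         call. = FALSE)
  unname(schema$parent_of[[label]])
}

#' @rdname label_schema
#' @return `schema_children()`: character vector of child labels (possibly
#'   empty).
#' @export
schema_children <- function(schema, label) {
  stopifnot(inherits(schema, "label_schema"))
  names(schema$parent_of)[schema$parent_of == label]
}

#' @export
print.label_schema <- function(x, ...) {
  cat("<label_schema '", x$schema_id, "': ", length(x$labels),
      " labels rooted at 'trachea'>\n", sep = "")
  invisible(x)
}
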