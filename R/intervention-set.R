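#' Construct an InterventionSet
#'
#' @param members character vector of perturbed gene identifiers.
#' @param kind `"perturbagen"` (default) or `"disease"`.
#' @return an [InterventionSet-class].
#' @export
InterventionSet <- function(members, kind = "perturbagen") {
  new("InterventionSet", members = as.character(members), kind = kind)
}

#' Accessors for InterventionSet
#'
#' @param x an [InterventionSet-class].
#' @name InterventionSet-accessors
#' @aliases members interventionKind
NULL

#' @rdname InterventionSet-accessors
#' @export
setMethod("members", "InterventionSet", function(x) x@members)

#' @rdname InterventionSet-accessors
#' @export
setMethod("interventionKind", "InterventionSet", function(x) x@kind)

setMethod("show", "InterventionSet", function(object) {
  cat(sprintf("InterventionSet (%s): {%s}\n", object@kind,
              paste(object@members, collapse = ", ")))
})
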