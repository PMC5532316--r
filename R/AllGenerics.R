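#' Accessors for package classes
#'
#' \code{geneIds} returns the gene identifiers carried by an object;
#' \code{drugNames} the drug names of a set collection; \code{setMembers}
#' the member gene ids of one or all sets; \code{nInstances} the supporting
#' instance counts; \code{log2fcMatrix} and \code{delMatrix} the numeric
#' slots of a \linkS4class{SignatureSet}; \code{instanceInfo} its instance
#' table; \code{probeIds} the probe ids of a \linkS4class{ReannotationMap}
#' (all probes, or those of one gene).
#'
#' @param x an object.
#' @param gene,drug optional single identifier to restrict to.
#' @return See the individual accessor descriptions.
#' @name accessors
#' @aliases geneIds drugNames setMembers nInstances log2fcMatrix delMatrix
#'   instanceInfo probeIds
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("probeIds", function(x, gene = NULL) standardGeneric("probeIds"))

#' @rdname accessors
#' @export
setGeneric("drugNames", function(x) standardGeneric("drugNames"))

#' @rdname accessors
#' @export
setGeneric("setMembers", function(x, drug = NULL) standardGeneric("setMembers"))

#' @rdname accessors
#' @export
setGeneric("nInstances", function(x) standardGeneric("nInstances"))

#' @rdname accessors
#' @export
setGeneric("log2fcMatrix", function(x) standardGeneric("log2fcMatrix"))

#' @rdname accessors
#' @export
setGeneric("delMatrix", function(x) standardGeneric("delMatrix"))

#' @rdname accessors
#' @export
setGeneric("instanceInfo", function(x) standardGeneric("instanceInfo"))

#' @rdname accessors
setMethod("geneIds", "ReannotationMap", function(x) names(x@geneToProbes))

#' @rdname accessors
setMethod("probeIds", "ReannotationMap", function(x, gene = NULL) {
  if (is.null(gene)) return(sort(unlist(x@geneToProbes, use.names = FALSE)))
  if (!gene %in% names(x@geneToProbes))
    stop("gene not in map: ", gene)
  x@geneToProbes[[gene]]
})

#' @rdname accessors
setMethod("geneIds", "SignatureSet", function(x) rownames(x@log2fc))

#' @rdname accessors
setMethod("geneIds", "DrugSetCollection",
          function(x) sort(unique(unlist(x@sets, use.names = FALSE))))

#' @rdname accessors
setMethod("drugNames", "DrugSetCollection", function(x) names(x@sets))

#' @rdname accessors
setMethod("setMembers", "DrugSetCollection", function(x, drug = NULL) {
  if (is.null(drug)) return(x@sets)
  if (!drug %in% names(x@sets)) stop("drug not in collection: ", drug)
  x@sets[[drug]]
})

#' @rdname accessors
setMethod("nInstances", "DrugSetCollection", function(x) x@nInstances)

#' @rdname accessors
setMethod("log2fcMatrix", "SignatureSet", function(x) x@log2fc)

#' @rdname accessors
setMethod("delMatrix", "SignatureSet", function(x) x@dels)

#' @rdname accessors
setMethod("instanceInfo", "SignatureSet", function(x) x@instances)

setMethod("length", "DrugSetCollection", function(x) length(x@sets))

setMethod("show", "ReannotationMap", function(object) {
  cat(sprintf("ReannotationMap: %d lncRNA genes, %d probes\n",
              length(object@geneToProbes),
              length(unlist(object@geneToProbes, use.names = FALSE))))
  p <- object@params
  cat(sprintf("  probe_length=%d min_probes_per_gene=%d strand_mode=%s\n",
              p$probe_length, p$min_probes_per_gene, p$strand_mode))
  if (length(object@provenance))
    cat("  provenance:",
        paste(names(object@provenance), unlist(object@provenance),
              sep = "=", collapse = " "), "\n")
})

setMethod("show", "SignatureSet", function(object) {
  cat(sprintf("SignatureSet: %d genes x %d instances (%d drugs)\n",
              nrow(object@log2fc), ncol(object@log2fc),
              length(unique(object@instances$drug_name))))
  cat(sprintf("  fc_threshold=%g, %d DEL calls\n",
              object@params$fc_threshold, sum(object@dels != 0L)))
})

setMethod("show", "DrugSetCollection", function(object) {
  cat(sprintf("DrugSetCollection: %d drug-induced lncRNA sets, %d genes\n",
              length(object@sets),
              length(unique(unlist(object@sets, use.names = FALSE)))))
  if (length(object@sets)) {
    sz <- lengths(object@sets)
    cat(sprintf("  set sizes: min %d / median %g / max %d\n",
                min(sz), stats::median(sz), max(sz)))
  }
})
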