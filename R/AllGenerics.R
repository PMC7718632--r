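# Accessor generics and show methods for the core classes.

#' @rdname FvCBParameters-class
#' @param object an object
#' @export
setGeneric("vcmax", function(object) standardGeneric("vcmax"))
#' @rdname FvCBParameters-class
#' @export
setGeneric("etr", function(object) standardGeneric("etr"))
#' @rdname FvCBParameters-class
#' @export
setGeneric("tpu", function(object) standardGeneric("tpu"))
#' @rdname FvCBParameters-class
#' @export
setGeneric("rd", function(object) standardGeneric("rd"))
#' @rdname AciCurve-class
#' @param object an object
#' @export
setGeneric("ciValues", function(object) standardGeneric("ciValues"))
#' @rdname AciCurve-class
#' @export
setGeneric("aValues", function(object) standardGeneric("aValues"))
#' @rdname AciCurve-class
#' @export
setGeneric("leafTemp", function(object) standardGeneric("leafTemp"))
#' @rdname AciFit-class
#' @param object an object
#' @export
setGeneric("fittedParameters", function(object) standardGeneric("fittedParameters"))
#' @rdname AciFit-class
#' @export
setGeneric("limitation", function(object) standardGeneric("limitation"))
#' @rdname AciFit-class
#' @export
setGeneric("sse", function(object) standardGeneric("sse"))
#' @rdname PotWaterState-class
#' @param object an object
#' @export
setGeneric("swc", function(object) standardGeneric("swc"))
#' @rdname PotWaterState-class
#' @export
setGeneric("waterContent", function(object) standardGeneric("waterContent"))
#' @rdname CorrelationMatrix-class
#' @param object an object
#' @export
setGeneric("corValues", function(object) standardGeneric("corValues"))
#' @rdname CorrelationMatrix-class
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))

#' @rdname FvCBParameters-class
#' @export
setMethod("vcmax", "FvCBParameters", function(object) object@vcmax)
#' @rdname FvCBParameters-class
#' @export
setMethod("etr", "FvCBParameters", function(object) object@j)
#' @rdname FvCBParameters-class
#' @export
setMethod("tpu", "FvCBParameters", function(object) object@tpu)
#' @rdname FvCBParameters-class
#' @export
setMethod("rd", "FvCBParameters", function(object) object@rd)

#' @rdname AciCurve-class
#' @export
setMethod("ciValues", "AciCurve", function(object) object@ci)
#' @rdname AciCurve-class
#' @export
setMethod("aValues", "AciCurve", function(object) object@a)
#' @rdname AciCurve-class
#' @export
setMethod("leafTemp", "AciCurve", function(object) object@leafTemp)

#' @rdname AciFit-class
#' @export
setMethod("fittedParameters", "AciFit", function(object) object@params)
#' @rdname AciFit-class
#' @export
setMethod("limitation", "AciFit", function(object) object@limitation)
#' @rdname AciFit-class
#' @export
setMethod("sse", "AciFit", function(object) object@sse)
#' @rdname AciFit-class
#' @export
setMethod("vcmax", "AciFit", function(object) object@params@vcmax)
#' @rdname AciFit-class
#' @export
setMethod("etr", "AciFit", function(object) object@params@j)
#' @rdname AciFit-class
#' @export
setMethod("tpu", "AciFit", function(object) object@params@tpu)

#' @rdname PotWaterState-class
#' @export
setMethod("swc", "PotWaterState",
          function(object) 100 * object@water / object@capacity)
#' @rdname PotWaterState-class
#' @export
setMethod("waterContent", "PotWaterState", function(object) object@water)

#' @rdname CorrelationMatrix-class
#' @export
setMethod("corValues", "CorrelationMatrix", function(object) object@r)
#' @rdname CorrelationMatrix-class
#' @export
setMethod("pValues", "CorrelationMatrix", function(object) object@p)

setMethod("show", "FvCBParameters", function(object) {
  cat(sprintf(
    "FvCBParameters @ %.1f C: Vcmax=%.2f  J=%s  TPU=%s  Rd=%.2f\n",
    object@temp, object@vcmax,
    if (is.na(object@j)) "NA" else sprintf("%.2f", object@j),
    if (is.na(object@tpu)) "NA" else sprintf("%.2f", object@tpu),
    object@rd))
  cat(sprintf("  kinetics: GammaStar=%.2f  Kc=%.1f  Ko=%.1f  O2=%.0f\n",
              object@gammaStar, object@kc, object@ko, object@o2))
})

setMethod("show", "AciCurve", function(object) {
  cat(sprintf("AciCurve '%s': %d points, Ci %.0f-%.0f umol mol-1, %.1f C\n",
              object@curveId, length(object@ci), min(object@ci),
              max(object@ci), object@leafTemp))
})

setMethod("show", "AciFit", function(object) {
  cat(sprintf("AciFit '%s' (SSE %.4g)\n", object@curveId, object@sse))
  show(object@params)
  cat("  limitation:", paste(object@limitation, collapse = " "), "\n")
  flags <- c(vcmax = object@vcmaxIdentifiable, j = object@jIdentifiable,
             tpu = object@tpuIdentifiable)
  cat("  identifiable:", paste(names(flags)[flags], collapse = ", "), "\n")
})

setMethod("show", "PotWaterState", function(object) {
  cat(sprintf("PotWaterState: %.1f / %.1f g (SWC %.1f%%)\n",
              object@water, object@capacity, swc(object)))
})

setMethod("show", "DesignSpec", function(object) {
  cat(sprintf(
    "DesignSpec: %d genotypes x 2 heat x 2 drought x %d blocks\n",
    length(object@genotypes), object@nBlocks))
  cat("  in-cabinet DAT:", paste(object@inCabinetDays, collapse = ","),
      " imaging DAT:", paste(object@imagingDays, collapse = ","),
      " gas exchange DAT:", paste(object@gasExchangeDays, collapse = ","),
      "\n")
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix (%s): %d traits\n",
              object@treatment, nrow(object@r)))
  print(round(object@r, 3))
})
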