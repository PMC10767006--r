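## Accessor generics. Slots are never accessed with @ outside the package.

#' @rdname UnloadedGeometry-class
#' @param object an object
#' @export
setGeneric("outerDiameter", function(object) standardGeneric("outerDiameter"))
#' @rdname UnloadedGeometry-class
#' @export
setGeneric("innerDiameter", function(object) standardGeneric("innerDiameter"))
#' @rdname UnloadedGeometry-class
#' @export
setGeneric("wallThickness", function(object) standardGeneric("wallThickness"))

#' @rdname InflationRecord-class
#' @param object an object
#' @export
setGeneric("axialStretch", function(object) standardGeneric("axialStretch"))
#' @rdname InflationRecord-class
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname BiaxialDataset-class
#' @param object an object
#' @export
setGeneric("records", function(object) standardGeneric("records"))
#' @rdname BiaxialDataset-class
#' @export
setGeneric("mapPressure", function(object) standardGeneric("mapPressure"))
#' @rdname BiaxialDataset-class
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @rdname BiaxialDataset-class
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname StressStrainCurve-class
#' @param object an object
#' @export
setGeneric("states", function(object) standardGeneric("states"))

#' @rdname OrientationHistogram-class
#' @param object an object
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))
#' @rdname OrientationHistogram-class
#' @export
setGeneric("binWeights", function(object) standardGeneric("binWeights"))

#' @rdname FiberImageStack-class
#' @param object an object
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname FiberImageStack-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname FiberImageStack-class
#' @export
setGeneric("zSpacing", function(object) standardGeneric("zSpacing"))
#' @rdname FiberImageStack-class
#' @export
setGeneric("channel", function(object) standardGeneric("channel"))
#' @rdname FiberImageStack-class
#' @export
setGeneric("nSlices", function(object) standardGeneric("nSlices"))
#' @rdname FiberImageStack-class
#' @param i slice index
#' @export
setGeneric("getSlice", function(object, i) standardGeneric("getSlice"))

setMethod("outerDiameter", "UnloadedGeometry",
          function(object) object@outerDiameter)
setMethod("innerDiameter", "UnloadedGeometry",
          function(object) object@innerDiameter)
setMethod("wallThickness", "UnloadedGeometry",
          function(object) (object@outerDiameter - object@innerDiameter) / 2)

setMethod("axialStretch", "InflationRecord",
          function(object) object@axialStretch)
setMethod("samples", "InflationRecord", function(object) object@samples)

setMethod("geometry", "BiaxialDataset", function(object) object@geometry)
setMethod("records", "BiaxialDataset", function(object) object@records)
setMethod("mapPressure", "BiaxialDataset", function(object) object@mapPressure)
setMethod("groupLabel", "BiaxialDataset", function(object) object@groupLabel)

setMethod("axialStretch", "StressStrainCurve",
          function(object) object@axialStretch)
setMethod("states", "StressStrainCurve", function(object) object@states)
setMethod("geometry", "StressStrainCurve", function(object) object@geometry)

setMethod("binCenters", "OrientationHistogram",
          function(object) object@binCenters)
setMethod("binWeights", "OrientationHistogram", function(object) object@weights)

setMethod("voxels", "FiberImageStack", function(object) object@voxels)
setMethod("pixelSize", "FiberImageStack", function(object) object@pixelSize)
setMethod("zSpacing", "FiberImageStack", function(object) object@zSpacing)
setMethod("channel", "FiberImageStack", function(object) object@channel)
setMethod("nSlices", "FiberImageStack",
          function(object) dim(object@voxels)[3])
setMethod("getSlice", "FiberImageStack",
          function(object, i) object@voxels[, , i])
setMethod("axialStretch", "FiberImageStack",
          function(object) object@axialStretch)

#' @rdname ConstitutiveParams-class
#' @param object an object
#' @export
setGeneric("fiberFamilies", function(object) standardGeneric("fiberFamilies"))
#' @rdname ConstitutiveParams-class
#' @export
setGeneric("matrixStiffness",
           function(object) standardGeneric("matrixStiffness"))
setMethod("fiberFamilies", "ConstitutiveParams",
          function(object) object@fiberFamilies)
setMethod("matrixStiffness", "ConstitutiveParams",
          function(object) object@matrixStiffness)
setMethod("geometry", "ConstitutiveParams", function(object) object@geometry)

#' @rdname InVivoStretchEstimate-class
#' @param object an object
#' @export
setGeneric("stretchValue", function(object) standardGeneric("stretchValue"))
#' @rdname InVivoStretchEstimate-class
#' @export
setGeneric("forceVariation",
           function(object) standardGeneric("forceVariation"))
#' @rdname InVivoStretchEstimate-class
#' @export
setGeneric("withinThreshold",
           function(object) standardGeneric("withinThreshold"))
#' @rdname InVivoStretchEstimate-class
#' @export
setGeneric("perRecord", function(object) standardGeneric("perRecord"))
setMethod("stretchValue", "InVivoStretchEstimate",
          function(object) object@value)
setMethod("forceVariation", "InVivoStretchEstimate",
          function(object) object@forceVariation)
setMethod("withinThreshold", "InVivoStretchEstimate",
          function(object) object@withinThreshold)
setMethod("perRecord", "InVivoStretchEstimate",
          function(object) object@perRecord)

#' @rdname DepthOrientationMap-class
#' @param object an object
#' @export
setGeneric("depths", function(object) standardGeneric("depths"))
#' @rdname DepthOrientationMap-class
#' @export
setGeneric("orientationMap",
           function(object) standardGeneric("orientationMap"))
#' @rdname DepthOrientationMap-class
#' @export
setGeneric("angles", function(object) standardGeneric("angles"))
setMethod("depths", "DepthOrientationMap", function(object) object@depths)
setMethod("angles", "DepthOrientationMap", function(object) object@angles)
setMethod("orientationMap", "DepthOrientationMap", function(object) object@map)
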