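## Orchestration: configuration, end-to-end scoring of a single mesh, and
## dataset-level evaluation reports.

.default_config <- function() {
  list(
    registration = list(stiffness = c(50, 20, 5, 2, 0.8), maxIter = 10L,
                        tol = 1e-4, cutoff = 50),
    nds = list(gridCount = 4515L, kernel = "gaussian", bandwidth = "scott",
               scottD = 3L),
    model = list(hidden = c(256L, 128L, 64L, 32L),
                 fractions = c(0.8, 0.1, 0.1), learningRate = 1e-3,
                 batchSize = 16L, maxEpochs = 200L, patience = 20L,
                 standardize = FALSE, seed = 1L),
    attribution = list(baseline = "zeros", steps = 128L),
    synthetic = list(nPerClass = 100L, severityRange = c(0, 1),
                     noiseSD = 0.5, subdivision = 4L, seed = 1L))
}

#' Resolved run configuration
#'
#' Merges a YAML configuration file (or list) over the declared defaults.
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path optional YAML file path or a named list of overrides
#' @return the resolved configuration list, with a `hash` attribute
#'   fingerprinting it
#' @export
runConfig <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    user <- if (is.character(path)) yaml::read_yaml(path) else path
    if (!is.list(user)) stop("configuration must be a YAML mapping")
    for (blk in names(user)) {
      if (!blk %in% names(cfg)) stop("unknown configuration block: ", blk)
      for (key in names(user[[blk]])) {
        if (!key %in% names(cfg[[blk]]))
          stop("unknown configuration key: ", blk, "$", key)
        cfg[[blk]][[key]] <- user[[blk]][[key]]
      }
    }
  }
  attr(cfg, "hash") <- configHash(cfg)
  cfg
}

#' Fingerprint an R object (FNV-1a over its JSON serialization)
#'
#' Embedded in reports and artifacts so any result can be traced to the
#' exact configuration that produced it.
#'
#' @param x an R object
#' @return an 8-hex-digit string
#' @export
configHash <- function(x) {
  attr(x, "hash") <- NULL
  bytes <- charToRaw(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                   digits = NA)))
  # 32-bit FNV-1a; the multiply is split into 16-bit halves so intermediate
  # products stay within exact double precision
  # the XOR touches only the low byte; the multiply is split into 16-bit
  # halves so every intermediate stays exactly representable as a double
  h <- 2166136261
  for (b in as.integer(bytes)) {
    lob <- h %% 256
    h <- h - lob + bitwXor(lob, b)
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

#' Evaluate a trained model on a labelled test set
#'
#' @param model an [NDSModel-class]
#' @param test an [NDSSet-class] with true labels (and optionally a
#'   `severity` column, enabling per-class Spearman correlation of the FP
#'   score against quartile-binned severity grades)
#' @return list with accuracy, per-class confusion matrix, the per-sample
#'   prediction table, and per-class Spearman correlations (NA when severity
#'   is absent)
#' @export
evaluateModel <- function(model, test) {
  stopifnot(is(model, "NDSModel"), is(test, "NDSSet"))
  if (ncol(test) == 0L) stop("empty test set")
  truth <- as.character(SummarizedExperiment::colData(test)$label)
  pred <- predictNDSSet(model, test)
  confusion <- table(truth = factor(truth, levels = model@classLabels),
                     predicted = factor(pred$predicted,
                                        levels = model@classLabels))
  accuracy <- mean(pred$predicted == truth)
  spearman <- setNames(rep(NA_real_, length(model@classLabels)),
                       model@classLabels)
  sev <- SummarizedExperiment::colData(test)$severity
  if (!is.null(sev)) {
    for (cl in model@classLabels) {
      sel <- truth == cl
      if (sum(sel) >= 4L && cl != model@classLabels[1L]) {
        fp <- predictNDSSet(model, test[, sel], scoreClass = cl)$rawFP
        grade <- gradeSeverity(sev[sel])
        spearman[cl] <- suppressWarnings(cor(fp, grade, method = "spearman"))
      }
    }
  }
  pred$truth <- truth
  list(accuracy = accuracy, confusion = confusion, samples = pred,
       spearman = spearman)
}

#' Score and explain a single head mesh end to end
#'
#' Runs clip -> rigid align (onto the template landmarks) -> non-rigid
#' registration (or `skipRegister` for meshes already on the template
#' topology) -> NDS extraction -> classification and FP scoring -> FP
#' percentile -> integrated-gradients attention map projected onto the
#' aligned mesh. Stages that fail abort with the stage name.
#'
#' @param mesh a [TriangleMesh-class]
#' @param landmarks the mesh's [LandmarkSet-class]
#' @param model a trained [NDSModel-class]
#' @param template from [makeTemplate()] (or any list with mesh + landmarks);
#'   its landmarks define the reference pose
#' @param grid the [SphereGrid-class] matching the model
#' @param kernel see [kernelConfig()]
#' @param skipRegister skip non-rigid registration (inputs already share the
#'   template topology)
#' @param regConfig see [nonRigidConfig()]
#' @param scoreClass optional class whose FP node to score
#' @param ig see [igConfig()]
#' @param flipClip reverse which side of the landmark plane is kept
#' @param order "clip-register" (default) clips the raw scan before fitting
#'   the template; "register-clip" aligns and registers first, then clips at
#'   the template's landmark plane
#' @return list with `fp` ([FPResult-class]), `attribution`
#'   ([AttributionVector-class]), `attention` ([VertexAttentionMap-class]),
#'   `nds`, `mesh` (the aligned/registered mesh the attention map lives on)
#' @export
runPipeline <- function(mesh, landmarks, model, template = makeTemplate(),
                        grid = sphereGrid(), kernel = kernelConfig(),
                        skipRegister = FALSE, regConfig = nonRigidConfig(),
                        scoreClass = NULL, ig = igConfig(),
                        flipClip = FALSE,
                        order = c("clip-register", "register-clip")) {
  order <- match.arg(order)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  clipped <- if (order == "clip-register")
    stage("clip", clipNasionTragus(mesh, landmarks, flip = flipClip))
  else mesh
  tf <- stage("align", rigidAlign(landmarks, template$landmarks))
  aligned <- stage("align", applyTransform(clipped, tf))
  if (skipRegister) {
    if (nrow(aligned@vertices) != nrow(template$mesh@vertices))
      stop("pipeline stage 'register' failed: --skip-register requires the ",
           "template topology, but vertex counts differ", call. = FALSE)
    work <- new("TriangleMesh", vertices = aligned@vertices,
                faces = template$mesh@faces,
                topologyId = template$mesh@topologyId)
  } else {
    reg <- stage("register", nonRigidICP(template$mesh, aligned, regConfig))
    work <- reg@mesh
  }
  if (order == "register-clip")
    work <- stage("clip",
                  clipNasionTragus(work, template$landmarks, flip = flipClip))
  normals <- stage("normals", vertexNormals(work))
  nds <- stage("extract", evaluateKDE(normals, grid, kernel))
  fp <- stage("predict", predictNDS(model, nds, scoreClass = scoreClass,
                                    normalize = TRUE))
  igc <- ig
  if (identical(igc$targetClass, "predicted")) igc$targetClass <- fp@scoredClass
  attr <- stage("explain", integratedGradients(model, nds, igc))
  att <- stage("explain", projectToVertices(attr, grid, normals))
  list(fp = fp, attribution = attr, attention = att, nds = nds, mesh = work)
}
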