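## Umbrella pipeline: ties the stages together, seeds everything from one
## config seed, and stamps every artifact with the seed and a config hash.

## FNV-1a 32-bit hash of a deparsed object; cheap, deterministic. The state
## is kept as a double and split into 16-bit halves for the multiply so all
## intermediates stay exactly representable.
configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    h <- (((h %/% 65536) * p) %% 65536) * 65536 + (h %% 65536) * p
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

pipelineDefaults <- function() {
  list(seed = 1, out_dir = NULL, n_boot = 1000,
       grid = seq(0.01, 1, by = 0.01), ci_level = 0.95,
       covariates = c("sex", "age", "bmi"),
       traits = "trait",
       stages = c("qst", "fst", "divergence", "sensitivity"),
       sim = list())
}

#' Run the divergence-testing pipeline
#'
#' Executes the toggled stages in order (qst, fst, divergence, sensitivity)
#' on supplied or simulated data and returns a per-trait summary (trait,
#' Qst, empirical p, critical c/h2) together with the stage objects. Every
#' randomized stage draws its seed deterministically from the single config
#' seed; written artifacts are stamped with the seed and a config hash so
#' reruns with the same config are byte-identical.
#'
#' @param config a named list (or path to a YAML file) overriding the
#'   defaults: \code{seed}, \code{out_dir} (NULL = no files written),
#'   \code{n_boot}, \code{grid}, \code{ci_level}, \code{covariates},
#'   \code{traits}, \code{stages} (subset of qst/fst/divergence/
#'   sensitivity), \code{pheno} (data.frame or TSV path), \code{genotypes}
#'   (\linkS4class{GenotypeMatrix} or TSV path), and \code{sim} (overrides
#'   for [simConfig()], used when data are not supplied)
#' @return (invisibly) list with \code{summary} data.frame, per-trait stage
#'   objects, and the resolved config
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipelineDefaults(), config)
  # hash the analysis parameters, not the data objects or output location
  hash <- configHash(cfg[setdiff(names(cfg),
                                 c("pheno", "genotypes", "out_dir"))])
  logMsg <- function(...) message("[qstfst] ", ...)

  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # inputs: supplied or simulated
  simCfg <- do.call(simConfig, utils::modifyList(list(seed = cfg$seed),
                                                 cfg$sim))
  genos <- NULL
  if (!is.null(cfg$genotypes)) {
    genos <- if (is(cfg$genotypes, "GenotypeMatrix")) cfg$genotypes
             else runStage("io", readGenotypes(cfg$genotypes))
  } else if (any(c("fst", "divergence") %in% cfg$stages)) {
    logMsg("simulating genotypes (", simCfg@nSnps, " SNPs, Fst target ",
           simCfg@targetFst, ")")
    genos <- runStage("simulate", simulateGenotypes(simCfg))
  }
  pheno <- NULL
  if (!is.null(cfg$pheno)) {
    pheno <- if (is.data.frame(cfg$pheno)) cfg$pheno
             else runStage("io", readPhenotypes(cfg$pheno))
  } else if (any(c("qst", "divergence", "sensitivity") %in% cfg$stages)) {
    logMsg("simulating phenotypes")
    pheno <- runStage("simulate", simulatePhenotype(genos, simCfg))
  }

  out <- list(config = cfg, hash = hash)
  fst <- NULL
  if ("fst" %in% cfg$stages) {
    logMsg("computing Weir-Cockerham theta")
    fst <- runStage("fst", wcTheta(genos))
    out$fst <- fst
  }

  summary <- NULL
  if ("qst" %in% cfg$stages) {
    covs <- intersect(cfg$covariates, names(pheno))
    perTrait <- lapply(cfg$traits, function(tr) {
      logMsg("trait '", tr, "': variance components and bootstrap")
      res <- list(vc = runStage("qst", varianceComponents(pheno, tr, covs)))
      if ("divergence" %in% cfg$stages) {
        boot <- runStage("divergence",
                         bootstrapQst(pheno, tr, covs, nBoot = cfg$n_boot,
                                      seed = cfg$seed))
        res$boot <- boot
        res$test <- runStage("divergence", qstFstTest(boot, fst))
        if ("sensitivity" %in% cfg$stages)
          res$sensitivity <- runStage("sensitivity",
            sensitivityCurve(boot, res$test, grid = cfg$grid,
                             ciLevel = cfg$ci_level))
      }
      res
    })
    names(perTrait) <- cfg$traits
    out$traits <- perTrait
    summary <- do.call(rbind, lapply(cfg$traits, function(tr) {
      res <- perTrait[[tr]]
      data.frame(
        trait = tr,
        qst = qstValue(res$vc)$qst,
        empirical_p = if (!is.null(res$test)) empiricalP(res$test) else NA,
        p_is_upper_bound = if (!is.null(res$test))
          res$test@pIsUpperBound else NA,
        critical_c_over_h2 = if (!is.null(res$sensitivity)) {
          if (res$sensitivity@criticalAboveMax)
            paste0(">", max(cfg$grid)) else
              as.character(criticalRatio(res$sensitivity))
        } else NA_character_,
        stringsAsFactors = FALSE)
    }))
    out$summary <- summary
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- list(seed = cfg$seed, config_hash = hash,
                  n_boot = cfg$n_boot)
    if (!is.null(summary)) {
      write.table(summary, file.path(cfg$out_dir, "divergence_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        c(stamp, list(summary = summary)),
        file.path(cfg$out_dir, "divergence_summary.json"),
        auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(fst)) {
      write.table(fst@perSnp, file.path(cfg$out_dir, "fst_per_snp.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        c(stamp, list(multi_locus_theta = multiLocusTheta(fst),
                      n_snps_used = fst@nUsed,
                      n_snps_excluded = fst@nExcluded)),
        file.path(cfg$out_dir, "fst_summary.json"),
        auto_unbox = TRUE, digits = NA)
    }
    logMsg("artifacts written to ", cfg$out_dir)
  }
  invisible(out)
}
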