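# The three-stage coarse -> fine -> accurate classifier: label grouping,
# per-node feature transforms (RF-importance subset, SpLPP embedding,
# gyroscope-channel mask), per-node CHMM banks and routed prediction.

#' Reshape a feature vector into a frame sequence
#'
#' Splits a length-p vector into T = ceiling(p/O) consecutive frames of O
#' coefficients; the final short frame is zero-padded. Each feature window
#' thereby becomes an observation sequence scorable by a CHMM on its own.
#'
#' @param vec numeric feature vector.
#' @param O frame width (coefficients per frame).
#' @return T x O numeric matrix.
#' @export
frame_sequence <- function(vec, O) {
  stopifnot(is.numeric(vec), length(vec) >= 1L)
  O <- as.integer(O)
  if (O < 1L) stop("O must be a positive integer")
  p <- length(vec)
  if (O > p) warning(sprintf("O = %d exceeds feature count %d: single zero-padded frame", O, p))
  Tn <- ceiling(p / O)
  padded <- c(vec, numeric(Tn * O - p))
  matrix(padded, nrow = Tn, ncol = O, byrow = TRUE)
}

#' Indices of gyroscope-named feature channels
#'
#' @param feature_names character vector of channel names.
#' @param pattern substring identifying gyroscope channels (default
#'   \code{"Gyro"}, matched case-sensitively as a fixed string).
#' @return integer indices of matching names; errors when none match.
#' @export
gyro_mask <- function(feature_names, pattern = "Gyro") {
  stopifnot(length(feature_names) >= 1L)
  idx <- grep(pattern, feature_names, fixed = TRUE)
  if (length(idx) == 0L) {
    stop(sprintf("no feature names contain '%s'; gyro stage cannot run", pattern))
  }
  idx
}

#' Default three-stage hierarchy configuration
#'
#' The fixed activity tree: stage 1 splits moving \{1,2,3\} from
#' stationary \{4,5,6\}; stage 2 splits walking \{1\} from up/downstairs
#' \{2,3\} and laying \{6\} from sitting/standing \{4,5\}; stage 3 resolves
#' upstairs vs downstairs on gyroscope channels of the original feature
#' space and sitting vs standing on an SpLPP embedding of the
#' importance-selected subset. Every element can be overridden via
#' \code{...} (named top-level replacements) or a YAML file
#' (\code{\link{read_tschmm_config}}).
#'
#' @param ... named top-level overrides merged over the defaults
#'   (e.g. \code{splpp = list(d = 5)} replaces the whole splpp block).
#' @return a \code{tschmm_config} list.
#' @export
tschmm_config <- function(...) {
  cfg <- list(
    rfim = list(enabled = TRUE, ntree = 500L, mtry = NULL, repeats = 1L),
    splpp = list(d = 13L, lambda_l1 = 0.1, ridge = 1e-6, solver_tol = 1e-8),
    gyro = list(pattern = "Gyro"),
    em = list(max_iter = 100L, tol = 1e-5),
    variance_floor = 1e-3,
    nodes = list(
      stage1 = list(
        stage = 1L, transform = "rfim_subset", Q = 4L, M = 2L, O = 8L,
        groups = list(moving = c(1L, 2L, 3L), stationary = c(4L, 5L, 6L)),
        children = list(moving = "moving", stationary = "stationary")
      ),
      moving = list(
        stage = 2L, transform = "rfim_subset", Q = 4L, M = 3L, O = 8L,
        groups = list(walking = 1L, updown = c(2L, 3L)),
        children = list(updown = "updown")
      ),
      stationary = list(
        stage = 2L, transform = "rfim_subset", Q = 4L, M = 3L, O = 8L,
        groups = list(laying = 6L, sitstand = c(4L, 5L)),
        children = list(sitstand = "sitstand")
      ),
      updown = list(
        stage = 3L, transform = "gyro_mask", Q = 2L, M = 2L, O = 8L,
        groups = list(upstairs = 2L, downstairs = 3L),
        children = list()
      ),
      sitstand = list(
        stage = 3L, transform = "splpp_embed", Q = 2L, M = 2L, O = 8L,
        groups = list(sitting = 4L, standing = 5L),
        children = list()
      )
    )
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], overrides[[nm]])
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  class(cfg) <- "tschmm_config"
  validate_tschmm_config(cfg)
  cfg
}

#' Load a hierarchy configuration from a YAML file
#'
#' Top-level keys mirror \code{\link{tschmm_config}} sections
#' (\code{rfim}, \code{splpp}, \code{gyro}, \code{em},
#' \code{variance_floor}, \code{nodes}); omitted keys keep defaults.
#'
#' @param path YAML file path.
#' @return a \code{tschmm_config}.
#' @export
read_tschmm_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(tschmm_config, raw)
}

validate_tschmm_config <- function(cfg) {
  nodes <- cfg$nodes
  for (nm in names(nodes)) {
    nd <- nodes[[nm]]
    labs <- sort(unlist(nd$groups, use.names = FALSE))
    if (anyDuplicated(labs)) {
      stop(sprintf("node '%s': groups overlap", nm))
    }
    for (g in names(nd$groups)) {
      if (length(nd$groups[[g]]) > 1L && is.null(nd$children[[g]])) {
        stop(sprintf("node '%s': multi-label group '%s' has no child node", nm, g))
      }
      child <- nd$children[[g]]
      if (!is.null(child)) {
        if (is.null(nodes[[child]])) {
          stop(sprintf("node '%s': unknown child node '%s'", nm, child))
        }
        child_labs <- sort(unlist(nodes[[child]]$groups, use.names = FALSE))
        if (!identical(as.integer(child_labs), as.integer(sort(nd$groups[[g]])))) {
          stop(sprintf("node '%s': child '%s' does not cover group '%s' exactly",
                       nm, child, g))
        }
      }
    }
  }
  root_labs <- sort(unlist(nodes[[1L]]$groups, use.names = FALSE))
  if (!identical(as.integer(root_labs), 1:6)) {
    stop("root node groups must cover the labels 1..6 exactly")
  }
  invisible(cfg)
}

# Apply a fitted node transform to a matrix of original-space rows.
apply_node_transform <- function(model, node_name, X) {
  tr <- model$transforms[[node_name]]
  switch(tr$type,
    identity = X,
    rfim_subset = X[, tr$indices, drop = FALSE],
    gyro_mask = X[, tr$indices, drop = FALSE],
    splpp_embed = lpp_transform(tr$projection, X[, tr$indices, drop = FALSE]),
    stop("unknown transform type: ", tr$type)
  )
}

#' Train the three-stage CHMM classifier
#'
#' Runs random-forest importance selection on the full training split,
#' then for every decision node restricts the windows to the node's
#' labels, applies the node's transform (importance subset at stages 1-2;
#' SpLPP embedding fitted on the node's own training pool for the
#' sitting/standing node; gyroscope mask over the original, unselected
#' feature space for the upstairs/downstairs node), reshapes each window
#' into a frame sequence, and fits one Gaussian-mixture CHMM per branch by
#' Baum-Welch.
#'
#' @param config a \code{tschmm_config}.
#' @param train a \code{har_dataset} containing every leaf label 1..6.
#' @param seed integer seed governing the forest and all CHMM
#'   initializations.
#' @return a \code{tschmm_model}: fitted transforms, per-node CHMM banks,
#'   the importance result, a config snapshot and a training log.
#' @export
train_tschmm <- function(config, train, seed) {
  stopifnot(inherits(config, "tschmm_config"), inherits(train, "har_dataset"))
  missing_labs <- setdiff(1:6, unique(train$y))
  if (length(missing_labs) > 0L) {
    stop("training data is missing label(s): ", paste(missing_labs, collapse = ", "))
  }
  seed <- as.integer(seed)
  p <- ncol(train$X)
  if (isTRUE(config$rfim$enabled)) {
    rfim <- compute_importance(train, ntree = config$rfim$ntree,
                               mtry = config$rfim$mtry, seed = seed,
                               repeats = config$rfim$repeats)
    selected <- rfim$selected
  } else {
    rfim <- NULL
    selected <- seq_len(p)
  }
  transforms <- list()
  banks <- list()
  node_O <- list()
  log <- list()
  node_names <- names(config$nodes)
  for (ni in seq_along(node_names)) {
    nm <- node_names[ni]
    nd <- config$nodes[[nm]]
    node_labels <- unlist(nd$groups, use.names = FALSE)
    rows <- which(train$y %in% node_labels)
    tr <- switch(nd$transform,
      identity = list(type = "identity"),
      rfim_subset = list(type = "rfim_subset", indices = selected),
      gyro_mask = list(
        type = "gyro_mask",
        indices = gyro_mask(train$feature_names, config$gyro$pattern)
      ),
      splpp_embed = {
        base <- train$X[rows, selected, drop = FALSE]
        d_use <- min(config$splpp$d, ncol(base))
        graph <- sparse_reconstruction_weights(
          base, lambda_l1 = config$splpp$lambda_l1,
          solver_tol = config$splpp$solver_tol
        )
        proj <- lpp_project(base, graph, d = d_use, ridge = config$splpp$ridge)
        list(type = "splpp_embed", indices = selected, projection = proj,
             d = d_use)
      },
      stop(sprintf("node '%s': unknown transform '%s'", nm, nd$transform))
    )
    transforms[[nm]] <- tr
    model_tmp <- list(transforms = transforms)
    Xnode <- apply_node_transform(model_tmp, nm, train$X[rows, , drop = FALSE])
    ynode <- train$y[rows]
    bank_models <- list()
    # frame width never exceeds the node's transformed dimension
    o_use <- min(nd$O, ncol(Xnode))
    node_O[[nm]] <- o_use
    node_log <- list(input_dim = ncol(Xnode), n_windows = nrow(Xnode),
                     O = o_use)
    for (gi in seq_along(nd$groups)) {
      g <- names(nd$groups)[gi]
      gr_rows <- which(ynode %in% nd$groups[[g]])
      if (length(gr_rows) == 0L) {
        stop(sprintf("node '%s': no training windows for group '%s'", nm, g))
      }
      seqs <- lapply(gr_rows, function(r) frame_sequence(Xnode[r, ], o_use))
      g_seed <- seed + ni * 1000L + gi * 100L
      init <- init_chmm(nd$Q, nd$M, ncol(seqs[[1L]]), seqs, seed = g_seed,
                        variance_floor = config$variance_floor)
      fit <- baum_welch_fit(init, seqs, max_iter = config$em$max_iter,
                            tol = config$em$tol)
      bank_models[[g]] <- fit
      trace <- attr(fit, "loglik_trace")
      node_log[[g]] <- list(n_seq = length(seqs),
                            final_loglik = trace[length(trace)],
                            iterations = length(trace))
    }
    banks[[nm]] <- chmm_bank(bank_models)
    log[[nm]] <- node_log
  }
  structure(
    list(
      transforms = transforms, banks = banks, node_O = node_O, rfim = rfim,
      selected = selected, feature_names = train$feature_names,
      config = config, log = log, seed = seed
    ),
    class = "tschmm_model"
  )
}

#' Predict activity labels with a trained three-stage model
#'
#' Each window is routed from the root node to a leaf; at every node the
#' branch whose CHMM assigns the maximal forward log-likelihood wins, with
#' ties broken towards the branch containing the smallest activity code.
#'
#' @param model a \code{tschmm_model}.
#' @param test a \code{har_dataset} with the training feature names.
#' @param return_trace if \code{TRUE}, attach a per-window data frame of
#'   node decisions as \code{attr(, "trace")}.
#' @return integer vector of predicted labels (codes 1..6).
#' @export
predict_tschmm <- function(model, test, return_trace = FALSE) {
  stopifnot(inherits(model, "tschmm_model"), inherits(test, "har_dataset"))
  if (!identical(test$feature_names, model$feature_names)) {
    stop("test feature names are incompatible with the training features")
  }
  nodes <- model$config$nodes
  n <- nrow(test$X)
  preds <- integer(n)
  trace <- if (return_trace) {
    data.frame(stage1 = character(n), stage2 = character(n),
               stage3 = character(n), stringsAsFactors = FALSE)
  } else NULL
  # transform every window once per node (each node sees the ORIGINAL row)
  node_inputs <- lapply(names(nodes), function(nm) {
    apply_node_transform(model, nm, test$X)
  })
  names(node_inputs) <- names(nodes)
  for (i in seq_len(n)) {
    nm <- names(nodes)[1L]
    repeat {
      nd <- nodes[[nm]]
      bank <- model$banks[[nm]]
      o_i <- if (!is.null(model$node_O[[nm]])) model$node_O[[nm]] else nd$O
      seq_i <- frame_sequence(node_inputs[[nm]][i, ], o_i)
      lls <- vapply(bank$models, forward_loglik, numeric(1L), sequence = seq_i)
      if (all(!is.finite(lls))) stop("window ", i, " is unscorable at node ", nm)
      # deterministic tie-break: branches ordered by their smallest label code
      ord <- order(vapply(nd$groups[names(lls)], min, numeric(1L)))
      win <- names(lls)[ord][which.max(lls[ord])]
      if (return_trace) trace[i, nd$stage] <- win
      child <- nd$children[[win]]
      if (is.null(child)) {
        preds[i] <- as.integer(nd$groups[[win]][1L])
        break
      }
      nm <- child
    }
  }
  if (return_trace) attr(preds, "trace") <- trace
  preds
}

#' @export
print.tschmm_model <- function(x, ...) {
  cat(sprintf("tschmm_model: %d nodes, %d original features, %d selected (seed %d)\n",
              length(x$banks), length(x$feature_names), length(x$selected),
              x$seed))
  for (nm in names(x$banks)) {
    cat(sprintf("  %-10s transform=%-12s dim=%d groups=%s\n", nm,
                x$transforms[[nm]]$type, x$log[[nm]]$input_dim,
                paste(names(x$banks[[nm]]$models), collapse = "/")))
  }
  invisible(x)
}

#' Serialize a trained three-stage model to a JSON file
#' @param model a \code{tschmm_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
tschmm_save <- function(model, path) {
  stopifnot(inherits(model, "tschmm_model"))
  ser_tr <- lapply(model$transforms, function(tr) {
    out <- list(type = tr$type)
    if (!is.null(tr$indices)) out$indices <- tr$indices
    if (!is.null(tr$projection)) {
      out$projection <- list(
        A = as.vector(tr$projection$A), p = nrow(tr$projection$A),
        d = tr$projection$d, eigenvalues = tr$projection$eigenvalues,
        ridge = tr$projection$ridge
      )
    }
    out
  })
  ser_banks <- lapply(model$banks, function(b) {
    lapply(b$models, function(m) jsonlite::fromJSON(chmm_to_json(m)))
  })
  payload <- list(
    feature_names = model$feature_names, selected = model$selected,
    node_O = model$node_O,
    transforms = ser_tr, banks = ser_banks,
    config = unclass(model$config), seed = model$seed
  )
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' Load a three-stage model saved by \code{\link{tschmm_save}}
#' @param path JSON file path.
#' @return a \code{tschmm_model} (training log not preserved).
#' @export
tschmm_load <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  cfg_raw <- x$config
  cfg_raw$nodes <- lapply(cfg_raw$nodes, function(nd) {
    nd$groups <- lapply(nd$groups, as.integer)
    nd
  })
  config <- do.call(tschmm_config, cfg_raw)
  transforms <- lapply(x$transforms, function(tr) {
    out <- list(type = tr$type)
    if (!is.null(tr$indices)) out$indices <- as.integer(unlist(tr$indices))
    if (!is.null(tr$projection)) {
      pr <- tr$projection
      out$projection <- structure(
        list(A = matrix(as.numeric(unlist(pr$A)), pr$p, pr$d),
             eigenvalues = as.numeric(unlist(pr$eigenvalues)),
             d = pr$d, ridge = pr$ridge),
        class = "lpp_projection"
      )
      out$d <- pr$d
    }
    out
  })
  banks <- lapply(x$banks, function(b) {
    chmm_bank(lapply(b, function(m) {
      chmm_from_json(jsonlite::toJSON(m, digits = NA, auto_unbox = TRUE))
    }))
  })
  structure(
    list(
      transforms = transforms, banks = banks,
      node_O = lapply(x$node_O, as.integer), rfim = NULL,
      selected = as.integer(unlist(x$selected)),
      feature_names = as.character(unlist(x$feature_names)),
      config = config, log = NULL, seed = as.integer(x$seed)
    ),
    class = "tschmm_model"
  )
}
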