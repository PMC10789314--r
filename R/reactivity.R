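#' Descriptor names used by the reactivity classifier
#' @export
REACTIVITY_DESCRIPTORS <- c("fad_distance", "fad_angle", "anion_distance",
                            "energy_efficiency", "pkd_efficiency")

#' Affinity scorer backed by a lookup table
#'
#' Returns a scorer closure with the contract
#' `scorer(receptor, pose, ligand_id) -> pKd` used by [compute_descriptors()].
#' Values come from a table keyed by `(enzyme_id, ligand_id)`; pairs absent
#' from the table yield `NA` (a declared missing marker). External affinity
#' predictors (e.g. a CNN rescoring model) are consumed through this same
#' contract by supplying a custom closure instead.
#'
#' @param table data.frame with columns `enzyme_id`, `ligand_id`, `pkd`.
#' @return a scorer function.
#' @export
affinity_table_scorer <- function(table) {
  stopifnot(all(c("enzyme_id", "ligand_id", "pkd") %in% names(table)))
  key <- paste(table$enzyme_id, table$ligand_id, sep = "\r")
  val <- as.numeric(table$pkd)
  function(receptor, pose, ligand_id) {
    i <- match(paste(receptor$enzyme_id, ligand_id, sep = "\r"), key)
    if (is.na(i)) NA_real_ else val[i]
  }
}

#' Compute the five docking-derived reactivity descriptors
#'
#' For the representative pose of the top-ranked cluster:
#' `fad_distance` is the Euclidean distance from the mean ligand heavy-atom
#' coordinate to the FAD reference atom (C4alpha); `fad_angle` is the supplied
#' top-cluster ring-plane angle; `anion_distance` is the distance from the
#' designated anionic ligand atom to the CZ atom of the mapped active-site
#' arginine (R206 in reference numbering); `energy_efficiency` is the pose
#' energy per ligand heavy atom; `pkd_efficiency` is the predicted pKd per
#' ligand heavy atom.
#'
#' @param receptor a [complex_structure()].
#' @param top_pose representative [pose()] of the top-ranked cluster.
#' @param top_cluster_angle ring-plane angle of the top cluster, degrees.
#' @param fad_atom_name FAD reference atom name (default `"C4A"`).
#' @param anion_residue_number residue number of the active-site arginine in
#'   the receptor's own numbering.
#' @param anion_residue_atom atom name on that residue (default `"CZ"`).
#' @param ligand_anion_atom name of the anionic (phenolate oxygen) ligand atom.
#' @param scorer affinity scorer closure (see [affinity_table_scorer()]), or
#'   `NULL` to mark `pkd_efficiency` missing.
#' @param ligand_id ligand identifier forwarded to the scorer.
#' @return named numeric vector over [REACTIVITY_DESCRIPTORS]; unresolvable
#'   arginine or scorer values give `NA` with a warning.
#' @export
compute_descriptors <- function(receptor, top_pose, top_cluster_angle,
                                fad_atom_name = "C4A",
                                anion_residue_number = 206,
                                anion_residue_atom = "CZ",
                                ligand_anion_atom = "O1",
                                scorer = NULL, ligand_id = "ligand") {
  lig_xyz <- atom_coords(top_pose$atoms)
  n_heavy <- nrow(lig_xyz)
  i_fad <- which(receptor$fad$atom_name == fad_atom_name)
  if (length(i_fad) == 0L) {
    stop("FAD reference atom not found: ", fad_atom_name, call. = FALSE)
  }
  fad_xyz <- as.numeric(atom_coords(receptor$fad)[i_fad[1L], ])
  fad_distance <- vec_norm(colMeans(lig_xyz) - fad_xyz)

  i_lig <- which(top_pose$atoms$atom_name == ligand_anion_atom)
  if (length(i_lig) == 0L) {
    stop("ligand anion atom not found: ", ligand_anion_atom, call. = FALSE)
  }
  i_arg <- which(receptor$protein$resno == anion_residue_number &
                   receptor$protein$atom_name == anion_residue_atom)
  if (length(i_arg) == 0L) {
    warning("no ", anion_residue_atom, " atom at residue ",
            anion_residue_number, "; anion_distance set missing",
            call. = FALSE)
    anion_distance <- NA_real_
  } else {
    anion_distance <- vec_norm(
      as.numeric(lig_xyz[i_lig[1L], ]) -
        as.numeric(atom_coords(receptor$protein)[i_arg[1L], ]))
  }

  pkd <- if (is.null(scorer)) NA_real_ else
    scorer(receptor, top_pose, ligand_id)
  if (is.na(pkd) && !is.null(scorer)) {
    warning("affinity scorer returned no value for ", receptor$enzyme_id,
            " / ", ligand_id, "; pkd_efficiency set missing", call. = FALSE)
  }
  c(fad_distance = fad_distance,
    fad_angle = as.numeric(top_cluster_angle),
    anion_distance = anion_distance,
    energy_efficiency = top_pose$energy / n_heavy,
    pkd_efficiency = pkd / n_heavy)
}

#' Average descriptors across ligands into a consensus vector
#'
#' Arithmetic mean per descriptor over ligands with non-missing values;
#' a descriptor missing in every ligand stays missing.
#'
#' @param per_ligand matrix or data.frame of descriptor rows (one per ligand)
#'   sharing column names.
#' @return named numeric vector of consensus descriptors.
#' @export
consensus_descriptors <- function(per_ligand) {
  m <- as.matrix(as.data.frame(per_ligand))
  if (nrow(m) == 0L) stop("need at least one ligand row", call. = FALSE)
  if (anyNA(m)) {
    all_missing <- colSums(!is.na(m)) == 0L
    if (any(all_missing)) {
      warning("descriptor(s) missing for every ligand: ",
              paste(colnames(m)[all_missing], collapse = ", "), call. = FALSE)
    } else {
      warning("missing descriptor value(s) dropped from the consensus mean",
              call. = FALSE)
    }
  }
  colMeans(m, na.rm = TRUE)
}

#' Fit the logistic reactivity classifier
#'
#' Maximum-likelihood logistic regression of a binary reactive label on the
#' docking-derived descriptors, with Wald standard errors and p-values. If
#' the fit shows quasi-separation (non-convergence or fitted probabilities
#' pinned at 0/1), the model is refit with a small ridge penalty on the
#' non-intercept coefficients and flagged.
#'
#' @param descriptors data.frame or matrix of descriptor columns.
#' @param labels binary vector (0/1 or logical): 1 = reactive, i.e. any
#'   non-zero conversion with any ligand.
#' @param ridge ridge penalty used for the separation fallback (default 1e-4).
#' @return object of class `reactivity_model`: coefficients (incl.
#'   `(Intercept)`), `se`, `p_values`, `descriptors` (names fitted on),
#'   `ridge` (0 for the plain MLE fit), `separation` flag.
#' @export
fit_reactivity_model <- function(descriptors, labels, ridge = 1e-4) {
  x <- as.matrix(as.data.frame(descriptors))
  y <- as.numeric(labels)
  stopifnot(length(y) == nrow(x))
  keep <- stats::complete.cases(x) & !is.na(y)
  if (any(!keep)) {
    warning(sum(!keep), " row(s) with missing descriptors excluded from fit",
            call. = FALSE)
    x <- x[keep, , drop = FALSE]; y <- y[keep]
  }
  if (length(unique(y)) < 2L) {
    stop("degenerate fit: labels contain a single class", call. = FALSE)
  }
  if (nrow(x) < ncol(x) + 2L) {
    stop("too few rows (", nrow(x), ") for ", ncol(x), " descriptors",
         call. = FALSE)
  }
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1L) {
    drop_idx <- qrx$pivot[seq(qrx$rank + 1L, ncol(x) + 1L)] - 1L
    stop("collinear descriptors: ",
         paste(colnames(x)[drop_idx], collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(y = y, x)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!separation && !fit$converged) separation <- TRUE
  if (separation) {
    pen <- ridge_logistic(cbind(`(Intercept)` = 1, x), y, lambda = ridge)
    coefs <- pen$beta; se <- pen$se
    lambda_used <- ridge
  } else {
    sm <- summary(fit)
    coefs <- stats::coef(fit)
    se <- sm$coefficients[, "Std. Error"]
    lambda_used <- 0
  }
  z <- coefs / se
  pv <- 2 * stats::pnorm(-abs(z))
  structure(list(coefficients = coefs, se = se, p_values = pv,
                 descriptors = colnames(x), ridge = lambda_used,
                 separation = separation, n = nrow(x)),
            class = "reactivity_model")
}

# Ridge-penalized logistic regression by Newton iteration; the intercept
# (first column) is unpenalized. Used only as the quasi-separation fallback.
ridge_logistic <- function(X, y, lambda, max_iter = 200, tol = 1e-10) {
  p <- ncol(X)
  pen <- c(0, rep(lambda, p - 1L))
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X, y - mu)) - 2 * pen * beta
    H <- crossprod(X * w, X) + diag(2 * pen, p)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(H)))
  names(beta) <- names(se) <- colnames(X)
  list(beta = beta, se = se, iterations = it)
}

#' @export
print.reactivity_model <- function(x, ...) {
  cat(sprintf("<reactivity_model> n = %d, %s fit\n", x$n,
              if (x$ridge > 0) sprintf("ridge (lambda = %g, quasi-separation)",
                                       x$ridge) else "maximum-likelihood"))
  print(data.frame(coef = x$coefficients, se = x$se, p = x$p_values))
  invisible(x)
}

#' Predict reactivity from descriptors
#'
#' @param model a [fit_reactivity_model()] result.
#' @param descriptors named numeric vector, or data.frame/matrix of rows,
#'   covering the model's descriptor names.
#' @param threshold probability cutoff for the reactive call (default 0.5).
#' @return data.frame with `probability` and `label`
#'   (`"reactive"`/`"unreactive"`).
#' @export
predict_reactivity <- function(model, descriptors, threshold = 0.5) {
  if (is.null(dim(descriptors))) {
    descriptors <- as.data.frame(as.list(descriptors))
  }
  x <- as.data.frame(descriptors)
  missing <- setdiff(model$descriptors, names(x))
  if (length(missing) > 0L) {
    stop("missing descriptor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  xm <- as.matrix(x[, model$descriptors, drop = FALSE])
  eta <- drop(cbind(1, xm) %*%
                model$coefficients[c("(Intercept)", model$descriptors)])
  prob <- stats::plogis(eta)
  data.frame(probability = prob,
             label = ifelse(prob >= threshold, "reactive", "unreactive"),
             stringsAsFactors = FALSE)
}

#' Serialize / restore a reactivity model as JSON
#'
#' @param model a `reactivity_model`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `reactivity_model` (read).
#' @export
write_reactivity_model <- function(model, path) {
  jsonlite::write_json(
    list(descriptors = model$descriptors,
         coefficients = as.list(model$coefficients),
         se = as.list(model$se), p_values = as.list(model$p_values),
         ridge = model$ridge, separation = model$separation, n = model$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reactivity_model
#' @export
read_reactivity_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(j$coefficients),
                 se = unlist(j$se), p_values = unlist(j$p_values),
                 descriptors = j$descriptors, ridge = j$ridge,
                 separation = j$separation, n = j$n),
            class = "reactivity_model")
}
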