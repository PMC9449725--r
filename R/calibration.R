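#' Root a tree on an outgroup and trim the outgroup tip
#'
#' Because branch length cannot be objectively divided between the
#' outgroup branch and the rest of the tree, the standard recipe for
#' penalized-likelihood dating is to root on the outgroup and then remove
#' it, leaving the next-most-basal lineage as an outgroup on a branch
#' with length estimated from the data. Path lengths between all retained
#' tips are preserved.
#'
#' @param tree An `ape::phylo`.
#' @param outgroup_tip Tip label, present exactly once.
#' @return A rooted `phylo` lacking `outgroup_tip`.
#' @export
root_and_trim <- function(tree, outgroup_tip) {
  n <- sum(tree$tip.label == outgroup_tip)
  if (n == 0L) stop("outgroup tip '", outgroup_tip, "' not in tree",
                    call. = FALSE)
  if (n > 1L) stop("outgroup tip '", outgroup_tip, "' duplicated",
                   call. = FALSE)
  rooted <- ape::root(tree, outgroup = outgroup_tip, resolve.root = TRUE)
  out <- ape::drop.tip(rooted, outgroup_tip)
  if (!ape::is.rooted(out)) out <- ape::root(out, node = length(out$tip.label) + 1L)
  out
}

#' Read a fossil calibration table
#'
#' CSV with columns `id`, `fossil_name`, `clade_name`, `placement`
#' (`stem`/`crown`), `anchor1`, `anchor2`, `min_age`, `period`,
#' `citation`.
#'
#' @param path CSV path.
#' @return A tibble of calibrations.
#' @export
read_calibrations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "fossil_name", "clade_name", "placement", "anchor1",
            "anchor2", "min_age")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("calibration table missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(df$min_age > 0), all(df$placement %in% c("stem", "crown")))
  tibble::as_tibble(df)
}

#' @rdname read_calibrations
#' @param calibrations A calibration tibble.
#' @export
write_calibrations <- function(calibrations, path) {
  utils::write.csv(calibrations, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# deterministic representative tip pair whose MRCA is `node`
defining_tip_pair <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  first_tip <- function(nd) sort(tips_under(tree, nd))[1]
  sort(c(first_tip(kids[1]), first_tip(kids[2])))
}

#' Bind fossil calibrations to tree nodes
#'
#' A crown calibration constrains the MRCA of its anchor taxa (those
#' present in the tree); a stem calibration constrains that MRCA's parent
#' node. When only one anchor of a stem calibration is sampled, the stem
#' is that tip's parent. Calibrations that cannot be bound — fewer
#' anchors present than the placement needs, or a stem whose crown MRCA
#' is already the root — are reported as unassignable, never silently
#' dropped.
#'
#' @param tree A rooted `ape::phylo`.
#' @param calibrations Calibration tibble (see [read_calibrations()]).
#' @return A list with `assigned` (tibble: calibration columns plus
#'   `node`, `tip_a`, `tip_b` — a tip pair whose MRCA is the node) and
#'   `unassignable` (tibble: `id`, `reason` of `missing_anchor` or
#'   `stem_at_root`).
#' @export
assign_calibration_nodes <- function(tree, calibrations) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  assigned <- list()
  unass <- list()
  for (i in seq_len(nrow(calibrations))) {
    cal <- calibrations[i, ]
    anchors <- intersect(c(cal$anchor1, cal$anchor2), tree$tip.label)
    need <- if (cal$placement == "crown") 2L else 1L
    if (length(anchors) < need) {
      unass[[length(unass) + 1L]] <-
        tibble::tibble(id = cal$id, reason = "missing_anchor")
      next
    }
    crown <- if (length(anchors) >= 2L) ape::getMRCA(tree, anchors) else
      tree$edge[tree$edge[, 2] == which(tree$tip.label == anchors), 1]
    node <- if (cal$placement == "crown") crown else {
      if (length(anchors) == 1L) {
        crown  # already the tip's parent
      } else if (crown == root) {
        unass[[length(unass) + 1L]] <-
          tibble::tibble(id = cal$id, reason = "stem_at_root")
        next
      } else {
        tree$edge[tree$edge[, 2] == crown, 1]
      }
    }
    pair <- defining_tip_pair(tree, node)
    assigned[[length(assigned) + 1L]] <-
      dplyr::bind_cols(cal, tibble::tibble(node = node, tip_a = pair[1],
                                           tip_b = pair[2]))
  }
  list(
    assigned = if (length(assigned)) dplyr::bind_rows(assigned) else
      tibble::tibble(),
    unassignable = if (length(unass)) dplyr::bind_rows(unass) else
      tibble::tibble(id = character(), reason = character())
  )
}

#' Resolve fossils assigned to the same node
#'
#' When several fossils bind to one node (e.g. stems of sister families),
#' the fossil with the oldest minimum age is kept — younger fossils on
#' the same node add no information. Age ties break by lexicographically
#' smallest calibration id; superseded calibrations are reported with the
#' winner's id.
#'
#' @param assignments The `assigned` tibble from
#'   [assign_calibration_nodes()].
#' @return A list with `kept` (deduplicated assignments) and `superseded`
#'   (tibble: `id`, `superseded_by`).
#' @export
resolve_redundant_calibrations <- function(assignments) {
  if (nrow(assignments) == 0L) {
    return(list(kept = assignments,
                superseded = tibble::tibble(id = character(),
                                            superseded_by = character())))
  }
  keep_idx <- integer()
  sup <- list()
  for (nd in sort(unique(assignments$node))) {
    idx <- which(assignments$node == nd)
    ord <- idx[order(-assignments$min_age[idx], assignments$id[idx])]
    keep_idx <- c(keep_idx, ord[1])
    if (length(ord) > 1L) {
      sup[[length(sup) + 1L]] <-
        tibble::tibble(id = assignments$id[ord[-1]],
                       superseded_by = assignments$id[ord[1]])
    }
  }
  list(kept = assignments[sort(keep_idx), , drop = FALSE],
       superseded = if (length(sup)) dplyr::bind_rows(sup) else
         tibble::tibble(id = character(), superseded_by = character()))
}

#' Emit a penalized-likelihood dating configuration
#'
#' Writes the treePL-dialect configuration: one `mrca`/`min` block per
#' fossil constraint (all fossil constraints are minimum ages), an
#' optional fixed root (emitted with equal `min` and `max`, by default
#' 475 Ma for the land-plant root), an optional stem-euphyllophyte
#' minimum (407.6 Ma) when its anchor tips are in the tree, and a
#' `smooth` value. [write_treepl_sweep()] emits one configuration per
#' smoothing value over a grid, by default the seven decades from 1e-12
#' to 1e-06; the run with the smallest reported chi-squared is then
#' chosen.
#'
#' @param assignments Deduplicated assignments (the `kept` element of
#'   [resolve_redundant_calibrations()]).
#' @param treefile Path written into the config.
#' @param numsites Number of alignment columns (>= 1).
#' @param smoothing Positive smoothing parameter.
#' @param fix_root Emit the fixed-age root constraint.
#' @param root_age Root age (Ma) used when `fix_root`.
#' @param root_tips Length-2 tip pair defining the root node; defaults to
#'   a pair spanning the root of `tree`.
#' @param euphyllophyte_tips Optional length-2 tip pair for the stem
#'   euphyllophyte minimum-age constraint; `NULL` to omit.
#' @param euphyllophyte_min Minimum age (Ma) for that constraint.
#' @param tree Optional `phylo` used to derive `root_tips` and to check
#'   that all constraint tips exist before writing.
#' @param thorough Emit the `thorough` flag.
#' @return The configuration as a single string.
#' @export
write_treepl_config <- function(assignments, treefile = "dated.tre",
                                numsites, smoothing = 1e-12,
                                fix_root = TRUE, root_age = 475,
                                root_tips = NULL,
                                euphyllophyte_tips = NULL,
                                euphyllophyte_min = 407.6,
                                tree = NULL, thorough = TRUE) {
  stopifnot(numsites >= 1, smoothing > 0)
  if (nrow(assignments) == 0L && !fix_root) {
    stop("no_constraints: nothing to calibrate", call. = FALSE)
  }
  if (!is.null(tree)) {
    if (is.null(root_tips) && fix_root) {
      root_tips <- defining_tip_pair(tree, length(tree$tip.label) + 1L)
    }
    all_cfg_tips <- c(assignments$tip_a, assignments$tip_b, root_tips,
                      euphyllophyte_tips)
    missing <- setdiff(all_cfg_tips, tree$tip.label)
    if (length(missing) > 0L) {
      stop("constraint tips absent from tree: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (fix_root && is.null(root_tips)) {
    stop("fix_root needs root_tips (or a tree to derive them)", call. = FALSE)
  }
  lines <- c(
    paste0("treefile = ", treefile),
    paste0("numsites = ", numsites)
  )
  lab <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  if (fix_root) {
    lines <- c(lines,
      paste("mrca = root", root_tips[1], root_tips[2]),
      paste("min = root", format(root_age)),
      paste("max = root", format(root_age)))
  }
  if (!is.null(euphyllophyte_tips)) {
    lines <- c(lines,
      paste("mrca = euphyllophytes_stem", euphyllophyte_tips[1],
            euphyllophyte_tips[2]),
      paste("min = euphyllophytes_stem", format(euphyllophyte_min)))
  }
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, ]
    lines <- c(lines,
      paste("mrca =", lab(a$id), a$tip_a, a$tip_b),
      paste("min =", lab(a$id), format(a$min_age)))
  }
  lines <- c(lines, paste0("smooth = ", format(smoothing, scientific = TRUE)))
  if (thorough) lines <- c(lines, "thorough")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @rdname write_treepl_config
#' @param dir Output directory for the sweep files.
#' @param smoothing_grid Smoothing values, one config each.
#' @param ... Passed to [write_treepl_config()].
#' @return `write_treepl_sweep()`: invisibly, the written file paths.
#' @export
write_treepl_sweep <- function(assignments, dir,
                               smoothing_grid = 10^seq(-12, -6), ...) {
  paths <- vapply(smoothing_grid, function(s) {
    p <- file.path(dir, sprintf("treepl_smooth_%s.cfg",
                                format(s, scientific = TRUE)))
    writeLines(write_treepl_config(assignments, smoothing = s, ...), p,
               sep = "")
    p
  }, character(1))
  invisible(paths)
}

#' Parse a treePL-dialect configuration
#'
#' @param text Configuration text (or a file path if `is_path`).
#' @param is_path Treat `text` as a file path.
#' @return A list: `treefile`, `numsites`, `smoothing`, `thorough`, and
#'   `constraints` — a tibble `label`, `tip_a`, `tip_b`, `min_age`,
#'   `max_age` (`NA` when absent).
#' @export
read_treepl_config <- function(text, is_path = FALSE) {
  lines <- if (is_path) readLines(text, warn = FALSE) else
    strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  get1 <- function(key) {
    m <- stringr::str_match(lines, paste0("^", key, "\\s*=\\s*(.+)$"))[, 2]
    m[!is.na(m)][1] %||% NA_character_
  }
  mr <- stringr::str_match(lines, "^mrca\\s*=\\s*(\\S+)\\s+(\\S+)\\s+(\\S+)$")
  mr <- mr[!is.na(mr[, 1]), , drop = FALSE]
  constraints <- tibble::tibble(label = mr[, 2], tip_a = mr[, 3],
                                tip_b = mr[, 4],
                                min_age = NA_real_, max_age = NA_real_)
  mins <- stringr::str_match(lines, "^min\\s*=\\s*(\\S+)\\s+(\\S+)$")
  maxs <- stringr::str_match(lines, "^max\\s*=\\s*(\\S+)\\s+(\\S+)$")
  for (m in list(list(mins, "min_age"), list(maxs, "max_age"))) {
    tab <- m[[1]][!is.na(m[[1]][, 1]), , drop = FALSE]
    for (j in seq_len(nrow(tab))) {
      constraints[constraints$label == tab[j, 2], m[[2]]] <-
        as.numeric(tab[j, 3])
    }
  }
  list(treefile = get1("treefile"),
       numsites = as.integer(get1("numsites")),
       smoothing = as.numeric(get1("smooth")),
       thorough = any(lines == "thorough"),
       constraints = constraints)
}

#' Check a dated tree against a configuration's constraints
#'
#' For every constraint in the parsed configuration, the age of the
#' constrained node (the MRCA of the constraint's tip pair) in the dated
#' ultrametric tree must be at least the minimum and at most the maximum
#' (when present).
#'
#' @param dated_tree A rooted, dated (ultrametric) `ape::phylo` with
#'   branch lengths in time units.
#' @param config A parsed configuration from [read_treepl_config()].
#' @param tol Numeric slack for comparisons.
#' @return A tibble of violations (`label`, `node_age`, `min_age`,
#'   `max_age`, `kind`); zero rows when the tree satisfies every
#'   constraint.
#' @export
validate_dated_tree <- function(dated_tree, config, tol = 1e-8) {
  ages <- ape::branching.times(dated_tree)
  n_tip <- length(dated_tree$tip.label)
  out <- list()
  cs <- config$constraints
  for (i in seq_len(nrow(cs))) {
    node <- ape::getMRCA(dated_tree, c(cs$tip_a[i], cs$tip_b[i]))
    age <- unname(ages[as.character(node)])
    if (!is.na(cs$min_age[i]) && age < cs$min_age[i] - tol) {
      out[[length(out) + 1L]] <- tibble::tibble(
        label = cs$label[i], node_age = age, min_age = cs$min_age[i],
        max_age = cs$max_age[i], kind = "below_min")
    }
    if (!is.na(cs$max_age[i]) && age > cs$max_age[i] + tol) {
      out[[length(out) + 1L]] <- tibble::tibble(
        label = cs$label[i], node_age = age, min_age = cs$min_age[i],
        max_age = cs$max_age[i], kind = "above_max")
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(label = character(), node_age = numeric(),
                   min_age = numeric(), max_age = numeric(),
                   kind = character())
}

#' Collect chi-squared values across a smoothing sweep
#'
#' Scans run logs for reported chi-squared values and flags the smoothing
#' value with the smallest one.
#'
#' @param values Named numeric vector (names = smoothing values as
#'   strings) or a character vector of log file paths, in which case the
#'   last line matching `chisq` in each file is parsed.
#' @return A tibble `smoothing`, `chisq`, `best` (logical; single TRUE at
#'   the minimum, ties broken by smaller smoothing).
#' @export
collect_smoothing_chisq <- function(values) {
  if (is.character(values)) {
    labels <- if (!is.null(names(values))) names(values) else values
    parsed <- vapply(values, function(p) {
      lines <- grep("chisq", readLines(p, warn = FALSE),
                    ignore.case = TRUE, value = TRUE)
      if (!length(lines)) return(NA_real_)
      as.numeric(stringr::str_match(lines[length(lines)],
                                    "([0-9.eE+-]+)\\s*$")[, 2])
    }, numeric(1), USE.NAMES = FALSE)
    values <- stats::setNames(parsed, labels)
  }
  sm <- as.numeric(names(values))
  ord <- order(values, sm)
  tibble::tibble(smoothing = sm, chisq = unname(values),
                 best = seq_along(values) == ord[1])
}
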