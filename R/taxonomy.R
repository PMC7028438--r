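#' Diagnostic label taxonomy
#'
#' Two-level labels for multi-lead ECG diagnosis. The coarse task
#' distinguishes normal rhythm (N) from four disease families: arrhythmia
#' (AR), myocardial infarction (MI), ventricular hypertrophy (VH) and atrial
#' hypertrophy (AH). The fine task splits the families into 14 subtypes plus
#' N: sinus arrhythmia (SA), atrial arrhythmia (AA), junctional arrhythmia
#' (JA), ventricular arrhythmia (VA), heart block (HB); anterior (AMI),
#' inferior (IMI) and lateral (LMI) myocardial infarction; left (LVH), right
#' (RVH) and biventricular (BVH) hypertrophy; left (LAH), right (RAH) and
#' biatrial (BAH) hypertrophy.
#'
#' @format Character vectors of class names, in canonical order.
#' @name taxonomy
NULL

#' @rdname taxonomy
#' @export
task1_classes <- function() c("N", "AR", "MI", "VH", "AH")

#' @rdname taxonomy
#' @export
task2_classes <- function() {
  c("N",
    "SA", "AA", "JA", "VA", "HB",
    "AMI", "IMI", "LMI",
    "LVH", "RVH", "BVH",
    "LAH", "RAH", "BAH")
}

# fine -> coarse parent table
.task2_parent <- c(
  N = "N",
  SA = "AR", AA = "AR", JA = "AR", VA = "AR", HB = "AR",
  AMI = "MI", IMI = "MI", LMI = "MI",
  LVH = "VH", RVH = "VH", BVH = "VH",
  LAH = "AH", RAH = "AH", BAH = "AH"
)

#' Map a fine (task-2) label to its coarse (task-1) family
#'
#' @param label2 Character vector of fine labels (see [task2_classes()]).
#' @return Character vector of coarse labels, same length.
#' @examples
#' map_task2_to_task1(c("N", "AMI", "HB"))
#' @export
map_task2_to_task1 <- function(label2) {
  bad <- setdiff(unique(label2), names(.task2_parent))
  if (length(bad) > 0) {
    stop("unknown fine-grained label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(.task2_parent[label2])
}

#' Validate a coarse/fine label pair
#'
#' Checks both labels are known and that the coarse label is the fine
#' label's family under the taxonomy.
#'
#' @param task1,task2 Single labels.
#' @return Invisibly, a list with fields `task1` and `task2`.
#' @export
label_pair <- function(task1, task2) {
  if (!task2 %in% task2_classes()) {
    stop("unknown fine-grained label: ", task2, call. = FALSE)
  }
  if (!identical(task1, map_task2_to_task1(task2))) {
    stop("label hierarchy violation: task1 '", task1,
         "' is not the family of task2 '", task2, "'", call. = FALSE)
  }
  invisible(list(task1 = task1, task2 = task2))
}
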