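Package: bfbmap
Title: Reconstruction of Local Genomic Maps from Complex Breakage-Fusion-Bridge Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects candidate breakage-fusion-bridge (BFB) events from structural-variant
    junctions and segment copy-number profiles, and reconstructs the rearranged local
    genomic map (the ordered, oriented segment path). Copy numbers of BFB building blocks
    (mono-chains and loops) are fitted by integer linear programming; the blocks are then
    assembled along a BFB DAG into a palindrome-like path. Tolerates imperfect fold-back
    inversions, deletions, duplications, insertions, translocations, oncovirus
    integration, read-linkage evidence, and multi-subclone profiles. Includes a
    fusion-breakage simulator and benchmarking metrics (CN accuracy, total CN error,
    SV precision/recall/F1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    processx,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
SystemRequirements: Python (>= 3.8) with scipy (>= 1.9) on the PATH (MILP backend)
Config/testthat/edition: 3
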