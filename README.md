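# posegrep

Structure-based virtual screens rank thousands of docked small molecules
by docking score, but scores alone are weak evidence: a high-scoring pose
may miss the one interaction that every known ligand of the target makes.
posegrep filters docked poses *after* docking. Each user-defined filter
combines

- a **SMARTS substructure** pattern (e.g. `[#7,#8]` — any nitrogen or
  oxygen atom; `cc` — an aromatic carbon–carbon bond),
- a **3D query point**, given either as a literal coordinate or as a
  named receptor atom (chain, residue id, atom name),
- a **distance cutoff** in Å, and
- an optional **exclude** flag.

A pose passes a filter when the minimum distance from any matched
substructure atom to the query point is within the cutoff (the exclude
flag inverts this); filters combine by Boolean AND; and a **compound**
passes when *at least one* of its docked poses passes all filters — so
plausible lower-scoring poses are no longer invisible behind an
implausible top-scoring one. The decision rule per filter is:

| has substructure | exclude set | within cutoff | result |
|---|---|---|---|
| no  | no  | n/a | Fail |
| no  | yes | n/a | Pass |
| yes | no  | no  | Fail |
| yes | no  | yes | Pass |
| yes | yes | no  | Pass |
| yes | yes | yes | Fail |

Screen quality before/after filtering is quantified on a labelled ranked
library by the enrichment factor

    EF_n = P_n / (n · P_T / T)

(positives among the top *n*, over the count expected under random
ordering of *T* compounds containing *P_T* positives), together with
top-*n* hit counts and percentile ranks. When scoring a filtered screen,
compounds that failed the filters are moved to the bottom of the ranked
list, preserving relative order (a stable partition).

Supported pose formats: PDBQT and PDB (multi-pose via MODEL/ENDMDL
blocks, as written by AutoDock Vina) and SDF (one pose per V2000 entry).
PDB/PDBQT files carry no bond orders, so three bond-assignment modes are
provided: **NONE** (geometric single-bond perception — every atom treated
as sp³, atoms bonded when closer than the sum of covalent radii plus
0.45 Å), **SMILES** (bond orders copied from a per-compound `.smi`
template via heavy-atom graph matching), and **OPENBABEL** (a subprocess
contract around an external PDB→SDF converter such as `obabel`, tried
with `-h` and then `-p 7.4`). SDF bond blocks are always used directly.
Aromatic or higher-order SMARTS can never match under NONE mode; the
package warns about such combinations up front.

## Worked example

Every input can be generated synthetically, with a known ground truth:

```r
library(posegrep)
fx <- make_pose_fixtures(fixture_spec(seed = 2, n_compounds = 6))
res <- run_screen(fx$receptor_path, fx$compounds_dir, fx$filters_path)
res
#> ScreenResult: 6 files seen; 2 passed, 4 failed, 0 skipped
res$out_lines
#> [1] "cmpd_0001.pdbqt" "cmpd_0005.pdb"
```

The default fixture filter requires a compound N or O atom within 5.5 Å
of the receptor's glycine-863 α-carbon — a hydrogen-bond-style
constraint anchored by `{"receptorAtom": {"chain": "A", "resid": 863,
"atomname": "CA"}}`. The same screen from the shell, with the per-pose
sidecar:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "posegrep.R", package = "posegrep"))') \
  receptor.pdb compounds/ filters.json --jobs 2 --verbose --out pass.txt
#> posegrep: 6 files seen, 2 passed, 4 failed, 0 skipped
head -4 pass.txt.detail.tsv
#> file    pose_index  filter_label        min_distance      verdict
#> cmpd_0001.pdbqt  1  [#7,#8]@A:863:CA    7.35840424276894  Fail
#> cmpd_0001.pdbqt  2  [#7,#8]@A:863:CA    10.6289785962716  Fail
#> cmpd_0001.pdbqt  3  [#7,#8]@A:863:CA    1.93805314684608  Pass
```

`cmpd_0001` passes only through its third pose — exactly the situation
pose filtering exists for. On the metrics side:

```r
lib <- make_ranked_library_fixture(seed = 1, T = 1561, P_T = 46,
                                   placement = c(1:5, 100:140))
enrichment_factor(lib, 10)   # 5 positives in the top 10
#> [1] 16.96739
```

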