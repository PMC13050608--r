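"""Minimal AnnData <-> CSV bridge.

Only the per-cell observation table crosses this bridge: the expression
matrix is never read or written. Two subcommands:

  dump-obs  --path STORE --kind h5ad|zarr --out CSV
      writes the obs table (index as first column ``__obs_id__``) to CSV
  write-obs --csv CSV --path STORE --kind h5ad|zarr
      builds an obs-only AnnData (X has zero columns) from a CSV whose
      first column is ``__obs_id__`` and writes it as .h5ad or a zarr store

Exit codes: 0 ok, 2 unreadable/unwritable store, 3 bad arguments.
"""
import argparse
import sys


def main() -> int:
    parser = argparse.ArgumentParser(prog="anndata_bridge")
    sub = parser.add_subparsers(dest="cmd", required=True)
    d = sub.add_parser("dump-obs")
    d.add_argument("--path", required=True)
    d.add_argument("--kind", choices=["h5ad", "zarr"], required=True)
    d.add_argument("--out", required=True)
    w = sub.add_parser("write-obs")
    w.add_argument("--csv", required=True)
    w.add_argument("--path", required=True)
    w.add_argument("--kind", choices=["h5ad", "zarr"], required=True)
    try:
        args = parser.parse_args()
    except SystemExit:
        return 3

    import warnings

    warnings.filterwarnings("ignore")
    import anndata as ad
    import numpy as np
    import pandas as pd

    if args.cmd == "dump-obs":
        try:
            if args.kind == "h5ad":
                adata = ad.read_h5ad(args.path, backed="r")
            else:
                adata = ad.read_zarr(args.path)
        except Exception as exc:  # noqa: BLE001 - report and exit
            print(f"failed to read {args.kind} store: {exc}", file=sys.stderr)
            return 2
        obs = adata.obs.copy()
        obs.insert(0, "__obs_id__", obs.index.astype(str))
        obs.to_csv(args.out, index=False)
        return 0

    df = pd.read_csv(args.csv, dtype={"__obs_id__": str})
    obs = df.set_index("__obs_id__")
    obs.index.name = None
    for col in obs.columns:
        if obs[col].dtype == object:
            obs[col] = pd.Categorical(obs[col])
    adata = ad.AnnData(obs=obs, X=np.zeros((obs.shape[0], 0)))
    try:
        if args.kind == "h5ad":
            adata.write_h5ad(args.path)
        else:
            adata.write_zarr(args.path)
    except Exception as exc:  # noqa: BLE001
        print(f"failed to write {args.kind} store: {exc}", file=sys.stderr)
        return 2
    return 0


if __name__ == "__main__":
    sys.exit(main())
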