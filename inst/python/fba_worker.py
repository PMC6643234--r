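"""Constraint-based analysis worker.

Reads a JSON job description, runs FBA/FVA on a genome-scale (or toy)
metabolic model with COBRApy, and writes a JSON result. Called by the R
package as a subprocess; not a user-facing script.

Job schema:
  model_path: SBML (.xml/.sbml) or BiGG-style JSON (.json) model file
  mode: "inspect" | "fba" | "fva"
  bounds: [{"reaction": id, "lower": num|null, "upper": num|null}, ...]
  objective: reaction id or null (keep the model's objective)
  reactions: [ids] for FVA (null = all reactions)
  fraction_of_optimum: float for FVA
  out: result path
"""

import json
import sys


def load_model(path):
    import cobra.io

    if path.endswith(".json"):
        return cobra.io.load_json_model(path)
    return cobra.io.read_sbml_model(path)


def main(job_path):
    with open(job_path) as fh:
        job = json.load(fh)

    result = {"ok": False}
    try:
        model = load_model(job["model_path"])
        model.solver = "glpk"

        for change in job.get("bounds") or []:
            rxn = model.reactions.get_by_id(change["reaction"])
            if change.get("lower") is not None:
                rxn.lower_bound = change["lower"]
            if change.get("upper") is not None:
                rxn.upper_bound = change["upper"]

        if job.get("objective"):
            model.objective = model.reactions.get_by_id(job["objective"])

        mode = job["mode"]
        if mode == "inspect":
            result["reactions"] = [
                {
                    "id": r.id,
                    "lower_bound": r.lower_bound,
                    "upper_bound": r.upper_bound,
                    "objective_coefficient": r.objective_coefficient,
                }
                for r in model.reactions
            ]
            result["n_metabolites"] = len(model.metabolites)
            result["ok"] = True
        elif mode == "fba":
            sol = model.optimize()
            result["status"] = sol.status
            if sol.status == "optimal":
                result["objective_value"] = sol.objective_value
                result["fluxes"] = {r.id: float(sol.fluxes[r.id]) for r in model.reactions}
                result["ok"] = True
            else:
                result["error"] = f"LP not optimal: status {sol.status}"
        elif mode == "fva":
            from cobra.flux_analysis import flux_variability_analysis

            sol = model.optimize()
            result["status"] = sol.status
            if sol.status != "optimal":
                result["error"] = f"LP not optimal: status {sol.status}"
            else:
                result["objective_value"] = sol.objective_value
                rxns = job.get("reactions") or None
                fva = flux_variability_analysis(
                    model,
                    reaction_list=rxns,
                    fraction_of_optimum=job.get("fraction_of_optimum", 1.0),
                )
                result["fva"] = {
                    rid: {"minimum": float(row["minimum"]), "maximum": float(row["maximum"])}
                    for rid, row in fva.iterrows()
                }
                result["ok"] = True
        else:
            result["error"] = f"unknown mode {mode!r}"
    except Exception as exc:  # propagate any failure as structured output
        result["error"] = f"{type(exc).__name__}: {exc}"

    with open(job["out"], "w") as fh:
        json.dump(result, fh)
    return 0 if result["ok"] else 3


if __name__ == "__main__":
    sys.exit(main(sys.argv[1]))
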