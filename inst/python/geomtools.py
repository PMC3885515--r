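"""Geometry backend for the fencescape R package.

Reads a JSON request (geometries as GeoJSON) from argv[1], writes a JSON
response to argv[2].  Only coarse-grained operations are exposed; all modeling
logic lives on the R side.
"""
import json
import math
import sys

from shapely.geometry import shape, mapping, LineString, MultiLineString, Point
from shapely.geometry.base import BaseGeometry
from shapely.ops import unary_union, linemerge
from shapely import make_valid


def to_geom(gj):
    return shape(gj) if gj is not None else None


def to_geoms(lst):
    return [shape(g) for g in lst]


def line_parts(geom):
    """Explode any geometry into its LineString components."""
    if geom.is_empty:
        return []
    t = geom.geom_type
    if t == "LineString":
        return [geom]
    if t in ("MultiLineString", "GeometryCollection"):
        out = []
        for g in geom.geoms:
            out.extend(line_parts(g))
        return out
    return []


def poly_parts(geom):
    if geom is None or geom.is_empty:
        return []
    t = geom.geom_type
    if t == "Polygon":
        return [geom]
    if t in ("MultiPolygon", "GeometryCollection"):
        out = []
        for g in geom.geoms:
            out.extend(poly_parts(g))
        return out
    return []


def merged_lines(geoms):
    u = unary_union(geoms)
    parts = line_parts(u)
    if not parts:
        return []
    m = linemerge(MultiLineString(parts))
    return line_parts(m) or [m] if m.geom_type == "LineString" else line_parts(m)


def out_lines(parts):
    return [mapping(p) for p in parts]


def op_repair(req):
    fixed, repaired, failed = [], [], []
    for i, gj in enumerate(req["geoms"]):
        g = shape(gj)
        if g.is_valid:
            fixed.append(mapping(g))
            continue
        f = make_valid(g)
        polys = poly_parts(f)
        if not polys:
            f = g.buffer(0)
            polys = poly_parts(f)
        if not polys:
            failed.append(i)
            fixed.append(gj)
        else:
            u = unary_union(polys)
            fixed.append(mapping(u))
            repaired.append(i)
    return {"geoms": fixed, "repaired": repaired, "failed": failed}


def op_dissolve(req):
    """Union polygons by group; returns one geometry per unique group id."""
    geoms = to_geoms(req["geoms"])
    groups = req["groups"]
    order, by_group = [], {}
    for g, k in zip(geoms, groups):
        if k not in by_group:
            by_group[k] = []
            order.append(k)
        by_group[k].append(g)
    out, areas = [], []
    for k in order:
        u = unary_union(by_group[k])
        out.append(mapping(u))
        areas.append(u.area)
    return {"groups": order, "geoms": out, "areas": areas}


def op_adjacency(req):
    """Pairs of polygons sharing boundary of positive length (edge adjacency)."""
    geoms = to_geoms(req["geoms"])
    import shapely

    tree = shapely.STRtree(geoms)
    pairs = []
    for i, g in enumerate(geoms):
        for j in [int(j) for j in tree.query(g) if int(j) > i]:
            inter = g.intersection(geoms[j])
            shared = sum(l.length for l in line_parts(inter))
            if shared > 1e-9:
                pairs.append([i, j, shared])
    return {"pairs": pairs}


def op_shared_with(req):
    """For each polygon in a, total boundary length shared with union groups b."""
    a = to_geoms(req["a"])
    b = to_geoms(req["b"])
    out = []
    for g in a:
        row = []
        for h in b:
            inter = g.intersection(h)
            row.append(sum(l.length for l in line_parts(inter)))
        out.append(row)
    return {"shared": out}


def op_outline_union(req):
    geoms = to_geoms(req["geoms"])
    bnds = [g.boundary for g in geoms if not g.is_empty]
    parts = merged_lines(bnds) if bnds else []
    return {"lines": out_lines(parts), "total_length": sum(p.length for p in parts)}


def op_clip_polys(req):
    mask = unary_union(to_geoms(req["mask"]))
    out, areas = [], []
    for g in to_geoms(req["geoms"]):
        c = g.intersection(mask)
        polys = poly_parts(c)
        if polys:
            u = unary_union(polys)
            out.append(mapping(u))
            areas.append(u.area)
        else:
            out.append(None)
            areas.append(0.0)
    return {"geoms": out, "areas": areas}


def op_erase_polys(req):
    mask = unary_union(to_geoms(req["mask"])) if req["mask"] else None
    out, areas = [], []
    for g in to_geoms(req["geoms"]):
        c = g.difference(mask) if mask is not None else g
        polys = poly_parts(c)
        if polys:
            u = unary_union(polys)
            out.append(mapping(u))
            areas.append(u.area)
        else:
            out.append(None)
            areas.append(0.0)
    return {"geoms": out, "areas": areas}


def op_explode_polys(req):
    """Union everything, return individual polygon parts with areas."""
    u = unary_union(to_geoms(req["geoms"]))
    parts = poly_parts(u)
    return {"geoms": [mapping(p) for p in parts], "areas": [p.area for p in parts]}


def op_intersects(req):
    a = to_geoms(req["a"])
    b = to_geoms(req["b"])
    pairs = []
    for i, g in enumerate(a):
        for j, h in enumerate(b):
            if g.intersects(h):
                pairs.append([i, j])
    return {"pairs": pairs}


def op_buffer_fences(req):
    """Flat-cap buffer -> dissolve -> boundary segments -> drop cap-length
    segments -> merge.  The square buffer end produces exactly one straight
    boundary segment of length 2*halfwidth across each road end; deleting
    segments of that exact length (within tol) removes the caps so fences do
    not bisect roads."""
    tol = req.get("tol", 0.01)
    cap_lens = []
    buffers = []
    for grp in req["groups"]:
        hw = grp["halfwidth"]
        cap_lens.append(grp.get("cap_len", 2 * hw))
        for gj in grp["lines"]:
            ln = shape(gj)
            if ln.length <= 0:
                continue
            buffers.append(ln.buffer(hw, cap_style="flat", join_style="mitre",
                                     mitre_limit=10.0))
    if not buffers:
        return {"lines": [], "total_length": 0.0}
    u = unary_union(buffers)
    segs = []
    for poly in poly_parts(u):
        for ring in [poly.exterior, *poly.interiors]:
            cs = list(ring.coords)
            for p0, p1 in zip(cs[:-1], cs[1:]):
                L = math.hypot(p1[0] - p0[0], p1[1] - p0[1])
                if any(abs(L - c) <= tol for c in cap_lens):
                    continue
                segs.append(LineString([p0, p1]))
    parts = merged_lines(segs) if segs else []
    return {"lines": out_lines(parts), "total_length": sum(p.length for p in parts)}


def op_offset_lines(req):
    """One-sided offsets (shapely offset_curve): positive = left of direction."""
    dist = req["dist"]
    sides = req.get("sides")  # +1 left / -1 right per line
    out = []
    for k, gj in enumerate(req["lines"]):
        ln = shape(gj)
        d = dist * (sides[k] if sides else 1)
        off = ln.offset_curve(d, join_style="mitre", mitre_limit=10.0)
        parts = line_parts(off)
        out.append([mapping(p) for p in parts])
    return {"lines": out}


def _line_mask(req):
    masks = []
    if req.get("mask"):
        masks.append(unary_union(to_geoms(req["mask"])))
    if req.get("mask_lines"):
        bd = req.get("buffer_dist", 0.0)
        masks.append(unary_union(to_geoms(req["mask_lines"])).buffer(
            bd, cap_style="round"))
    return unary_union(masks) if masks else None


def op_erase_lines(req):
    """Per input line: line minus mask interior.  With keep_boundary the
    portions lying exactly on the mask boundary are retained."""
    mask = _line_mask(req)
    keep_boundary = bool(req.get("keep_boundary", False))
    out, kept, removed = [], 0.0, 0.0
    for gj in req["lines"]:
        ln = shape(gj)
        if mask is None:
            out.append([mapping(p) for p in line_parts(ln)])
            kept += ln.length
            continue
        res = ln.difference(mask)
        parts = line_parts(res)
        if keep_boundary:
            onb = ln.intersection(mask.boundary)
            parts = merged_lines(parts + line_parts(onb))
        got = sum(p.length for p in parts)
        kept += got
        removed += ln.length - got
        out.append([mapping(p) for p in parts])
    return {"lines": out, "kept_length": kept, "removed_length": removed}


def op_clip_lines(req):
    mask = unary_union(to_geoms(req["mask"]))
    out = []
    for gj in req["lines"]:
        ln = shape(gj)
        parts = line_parts(ln.intersection(mask))
        out.append([mapping(p) for p in parts])
    return {"lines": out}


def op_lines_within_buffer(req):
    """Whole-feature containment of a-lines in the dist-buffer of b-lines."""
    b = to_geoms(req["b"])
    if not b:
        return {"within": [False] * len(req["a"])}
    buf = unary_union(b).buffer(req["dist"], cap_style="round")
    return {"within": [shape(g).within(buf) for g in req["a"]]}


def op_merge_lines(req):
    parts = merged_lines(to_geoms(req["lines"]))
    return {"lines": out_lines(parts), "total_length": sum(p.length for p in parts)}


def op_fill_holes(req):
    from shapely.geometry import Polygon, MultiPolygon

    out, areas = [], []
    for gj in req["geoms"]:
        g = shape(gj)
        parts = [Polygon(p.exterior) for p in poly_parts(g)]
        u = unary_union(parts)
        out.append(mapping(u))
        areas.append(u.area)
    return {"geoms": out, "areas": areas}


def op_write_geotiff(req):
    import numpy as np
    import tifffile

    vals = np.array(req["values"], dtype="float64")
    nodata = req.get("nodata", -9999.0)
    vals = np.where(np.isnan(vals), nodata, vals)
    cell = float(req["cell_size"])
    ox, oy_top = float(req["origin_x"]), float(req["origin_y_top"])
    # GeoTIFF georeferencing: tie raster (0,0) [top-left] to world coords
    tags = [
        (33550, "d", 3, [cell, cell, 0.0], True),                 # ModelPixelScale
        (33922, "d", 6, [0.0, 0.0, 0.0, ox, oy_top, 0.0], True),  # ModelTiepoint
        (34735, "H", 16, [1, 1, 0, 3,
                          1024, 0, 1, 1,      # GTModelType = projected
                          1025, 0, 1, 1,      # GTRasterType = PixelIsArea
                          3072, 0, 1, int(req.get("epsg", 32767))], True),
        (42113, "s", 0, str(nodata), True),                        # GDAL_NODATA
    ]
    tifffile.imwrite(req["path"], vals, extratags=tags)
    return {"path": req["path"]}


def op_read_geotiff(req):
    import numpy as np
    import tifffile

    with tifffile.TiffFile(req["path"]) as tf:
        page = tf.pages[0]
        vals = page.asarray().astype("float64")
        tags = {t.code: t.value for t in page.tags.values()}
    scale = list(tags.get(33550, (0, 0, 0)))
    tie = list(tags.get(33922, [0] * 6))
    nodata = tags.get(42113)
    if nodata is not None:
        nd = float(nodata)
        vals = np.where(vals == nd, np.nan, vals)
    return {
        "values": [[None if math.isnan(v) else v for v in row] for row in vals],
        "cell_size": scale[0],
        "origin_x": tie[3],
        "origin_y_top": tie[4],
    }


OPS = {name[3:]: fn for name, fn in list(globals().items())
       if name.startswith("op_")}


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    try:
        result = OPS[req["op"]](req)
        out = {"ok": True, "result": result}
    except Exception as exc:  # propagate as structured error to R
        import traceback
        out = {"ok": False, "error": f"{exc}\n{traceback.format_exc()}"}
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
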