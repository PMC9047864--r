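#!/usr/bin/env python
"""Independent oracle for the 107-feature radiomic bank.

Computes first-order, shape, GLCM, GLRLM, GLSZM, GLDM and NGTDM features of
an image/mask pair from the published feature definitions, using numpy,
scipy.ndimage (zone labelling), scikit-image (marching cubes) and trimesh
(mesh volume). Deliberately coded independently of the R package (different
algorithms where possible: scipy labelling, skimage meshing, explicit loops
for the texture matrices) so it can serve as a cross-implementation check.

Usage:
  python radiomic_oracle.py image.csv mask.csv nx ny nz sx sy sz bin_width

The CSV files hold the flattened voxel values in Fortran (column-major)
order, one value per line. Output: "name,value" lines for all 107 features.
"""
import sys
import numpy as np
from scipy import ndimage
from skimage import measure
import trimesh

EPS = 0.0


def discretize(img, mask, bw):
    vals = img[mask]
    lev = np.floor(vals / bw) - np.floor(vals.min() / bw) + 1
    lev = lev.astype(int)
    out = np.zeros(img.shape, dtype=int)
    out[mask] = lev
    return out, int(lev.max())


def first_order(img, mask, lev_arr, ng):
    x = img[mask]
    n = x.size
    res = {}
    counts = np.bincount(lev_arr[mask], minlength=ng + 1)[1:]
    p = counts / n
    pnz = p[p > 0]
    mu = x.mean()
    m2 = ((x - mu) ** 2).mean()
    m3 = ((x - mu) ** 3).mean()
    m4 = ((x - mu) ** 4).mean()
    p10, p25, p50, p75, p90 = np.percentile(x, [10, 25, 50, 75, 90])
    rob = x[(x >= p10) & (x <= p90)]
    res["Energy"] = float((x ** 2).sum())
    res["Entropy"] = float(-(pnz * np.log2(pnz)).sum())
    res["Minimum"] = float(x.min())
    res["10Percentile"] = float(p10)
    res["90Percentile"] = float(p90)
    res["Maximum"] = float(x.max())
    res["Mean"] = float(mu)
    res["Median"] = float(p50)
    res["InterquartileRange"] = float(p75 - p25)
    res["Range"] = float(x.max() - x.min())
    res["MeanAbsoluteDeviation"] = float(np.abs(x - mu).mean())
    res["RobustMeanAbsoluteDeviation"] = float(np.abs(rob - rob.mean()).mean())
    res["RootMeanSquared"] = float(np.sqrt((x ** 2).mean()))
    res["Skewness"] = float(m3 / m2 ** 1.5) if m2 > 0 else 0.0
    res["Kurtosis"] = float(m4 / m2 ** 2) if m2 > 0 else 0.0
    res["Variance"] = float(m2)
    res["Uniformity"] = float((p ** 2).sum())
    return res


def shape(mask, spacing):
    pad = np.pad(mask.astype(np.uint8), 1)
    v, f, _, _ = measure.marching_cubes(pad, level=0.5, spacing=tuple(spacing),
                                        method="lorensen")
    area = measure.mesh_surface_area(v, f)
    tm = trimesh.Trimesh(v, f, process=False)
    vol = abs(tm.volume)
    vu = np.unique(np.round(v * 1e6).astype(np.int64), axis=0) / 1e6
    dif = vu[:, None, :] - vu[None, :, :]
    sq = dif ** 2
    d3 = np.sqrt((sq.sum(-1)).max())
    dxy = np.sqrt((sq[..., 0] + sq[..., 1]).max())
    dxz = np.sqrt((sq[..., 0] + sq[..., 2]).max())
    dyz = np.sqrt((sq[..., 1] + sq[..., 2]).max())
    co = np.argwhere(mask) * np.asarray(spacing)
    n = co.shape[0]
    if n > 1:
        ev = np.sort(np.linalg.eigvalsh(np.cov(co.T)))[::-1]
        ev = np.clip(ev, 0, None)
    else:
        ev = np.zeros(3)
    res = {
        "MeshVolume": vol,
        "VoxelVolume": float(mask.sum() * np.prod(spacing)),
        "SurfaceArea": area,
        "SurfaceVolumeRatio": area / vol,
        "Sphericity": (36 * np.pi * vol ** 2) ** (1 / 3) / area,
        "Maximum3DDiameter": d3,
        "Maximum2DDiameterSlice": dxy,
        "Maximum2DDiameterColumn": dyz,
        "Maximum2DDiameterRow": dxz,
        "MajorAxisLength": 4 * np.sqrt(ev[0]),
        "MinorAxisLength": 4 * np.sqrt(ev[1]),
        "LeastAxisLength": 4 * np.sqrt(ev[2]),
        "Elongation": np.sqrt(ev[1] / ev[0]) if ev[0] > 0 else 0.0,
        "Flatness": np.sqrt(ev[2] / ev[0]) if ev[0] > 0 else 0.0,
    }
    return {k: float(vv) for k, vv in res.items()}


def angles_13():
    out = []
    for dz in (-1, 0, 1):
        for dy in (-1, 0, 1):
            for dx in (-1, 0, 1):
                if (dz, dy, dx) == (0, 0, 0):
                    continue
                if dz > 0 or (dz == 0 and dy > 0) or (dz == 0 and dy == 0 and dx > 0):
                    out.append((dx, dy, dz))
    return out


def glcm(lev, ng):
    shp = lev.shape
    feats = []
    for dx, dy, dz in angles_13():
        P = np.zeros((ng, ng))
        idx = np.argwhere(lev > 0)
        for x, y, z in idx:
            xx, yy, zz = x + dx, y + dy, z + dz
            if 0 <= xx < shp[0] and 0 <= yy < shp[1] and 0 <= zz < shp[2]:
                if lev[xx, yy, zz] > 0:
                    P[lev[x, y, z] - 1, lev[xx, yy, zz] - 1] += 1
        P = P + P.T
        s = P.sum()
        if s == 0:
            continue
        feats.append(glcm_one(P / s, ng))
    keys = feats[0].keys()
    return {k: float(np.mean([f[k] for f in feats])) for k in keys}


def glcm_one(P, ng):
    i = np.arange(1, ng + 1)
    I, J = np.meshgrid(i, i, indexing="ij")
    px = P.sum(1)
    py = P.sum(0)
    mux = (i * px).sum()
    muy = (i * py).sum()
    sx = np.sqrt(((i - mux) ** 2 * px).sum())
    sy = np.sqrt(((i - muy) ** 2 * py).sum())
    k = np.arange(0, ng)
    pxmy = np.array([P[np.abs(I - J) == kk].sum() for kk in k])
    ks = np.arange(2, 2 * ng + 1)
    pxpy = np.array([P[(I + J) == kk].sum() for kk in ks])

    def ent(v):
        v = v[v > 0]
        return -(v * np.log2(v)).sum()

    hx, hy, hxy = ent(px), ent(py), ent(P)
    pp = np.outer(px, py)
    nz = (P > 0) & (pp > 0)
    hxy1 = -(P[nz] * np.log2(pp[nz])).sum()
    hxy2 = ent(pp)
    da = (k * pxmy).sum()
    res = {}
    res["Autocorrelation"] = (I * J * P).sum()
    res["ClusterProminence"] = ((I + J - mux - muy) ** 4 * P).sum()
    res["ClusterShade"] = ((I + J - mux - muy) ** 3 * P).sum()
    res["ClusterTendency"] = ((I + J - mux - muy) ** 2 * P).sum()
    res["Contrast"] = ((I - J) ** 2 * P).sum()
    res["Correlation"] = ((I * J * P).sum() - mux * muy) / (sx * sy) \
        if sx > 0 and sy > 0 else 0.0
    res["DifferenceAverage"] = da
    res["DifferenceEntropy"] = ent(pxmy)
    res["DifferenceVariance"] = ((k - da) ** 2 * pxmy).sum()
    res["Id"] = (P / (1 + np.abs(I - J))).sum()
    res["Idm"] = (P / (1 + (I - J) ** 2)).sum()
    res["Idmn"] = (P / (1 + (I - J) ** 2 / ng ** 2)).sum()
    res["Idn"] = (P / (1 + np.abs(I - J) / ng)).sum()
    res["Imc1"] = (hxy - hxy1) / max(hx, hy) if max(hx, hy) > 0 else 0.0
    res["Imc2"] = np.sqrt(max(1 - np.exp(-2 * (hxy2 - hxy)), 0))
    res["InverseVariance"] = (pxmy[1:] / k[1:] ** 2).sum()
    res["JointAverage"] = mux
    res["JointEnergy"] = (P ** 2).sum()
    res["JointEntropy"] = hxy
    res["MaximumProbability"] = P.max()
    if ng == 1:
        res["MCC"] = 1.0
    else:
        px_s = np.where(px > 0, px, 1.0)
        py_s = np.where(py > 0, py, 1.0)
        Q = (P / px_s[:, None]) @ (P / py_s[None, :]).T
        evs = np.sort(np.real(np.linalg.eigvals(Q)))[::-1]
        res["MCC"] = np.sqrt(max(evs[1], 0))
    res["SumAverage"] = (ks * pxpy).sum()
    res["SumEntropy"] = ent(pxpy)
    res["SumSquares"] = ((I - mux) ** 2 * P).sum()
    return res


def rl_features(P, npix):
    nr = P.sum()
    i = np.arange(1, P.shape[0] + 1)[:, None]
    j = np.arange(1, P.shape[1] + 1)[None, :]
    p = P / nr
    pg = P.sum(1)
    pr = P.sum(0)
    mug = (i * p).sum()
    mur = (j * p).sum()
    pnz = p[p > 0]
    return {
        "ShortRunEmphasis": (P / j ** 2).sum() / nr,
        "LongRunEmphasis": (P * j ** 2).sum() / nr,
        "GrayLevelNonUniformity": (pg ** 2).sum() / nr,
        "GrayLevelNonUniformityNormalized": (pg ** 2).sum() / nr ** 2,
        "RunLengthNonUniformity": (pr ** 2).sum() / nr,
        "RunLengthNonUniformityNormalized": (pr ** 2).sum() / nr ** 2,
        "RunPercentage": nr / npix,
        "GrayLevelVariance": ((i - mug) ** 2 * p).sum(),
        "RunVariance": ((j - mur) ** 2 * p).sum(),
        "RunEntropy": -(pnz * np.log2(pnz)).sum(),
        "LowGrayLevelRunEmphasis": (P / i ** 2).sum() / nr,
        "HighGrayLevelRunEmphasis": (P * i ** 2).sum() / nr,
        "ShortRunLowGrayLevelEmphasis": (P / (i ** 2 * j ** 2)).sum() / nr,
        "ShortRunHighGrayLevelEmphasis": (P * i ** 2 / j ** 2).sum() / nr,
        "LongRunLowGrayLevelEmphasis": (P * j ** 2 / i ** 2).sum() / nr,
        "LongRunHighGrayLevelEmphasis": (P * i ** 2 * j ** 2).sum() / nr,
    }


def glrlm(lev, ng, npix):
    shp = lev.shape
    maxlen = max(shp)
    feats = []
    for dx, dy, dz in angles_13():
        P = np.zeros((ng, maxlen))
        visited = np.zeros(shp, dtype=bool)
        for x in range(shp[0]):
            for y in range(shp[1]):
                for z in range(shp[2]):
                    # start of a line: predecessor out of bounds
                    px_, py_, pz_ = x - dx, y - dy, z - dz
                    if 0 <= px_ < shp[0] and 0 <= py_ < shp[1] and 0 <= pz_ < shp[2]:
                        continue
                    # walk the line
                    cx, cy, cz = x, y, z
                    cur, runlen = 0, 0
                    while 0 <= cx < shp[0] and 0 <= cy < shp[1] and 0 <= cz < shp[2]:
                        v = lev[cx, cy, cz]
                        if v == cur and v > 0:
                            runlen += 1
                        else:
                            if cur > 0:
                                P[cur - 1, min(runlen, maxlen) - 1] += 1
                            cur, runlen = v, 1
                        cx, cy, cz = cx + dx, cy + dy, cz + dz
                    if cur > 0:
                        P[cur - 1, min(runlen, maxlen) - 1] += 1
        if P.sum() == 0:
            continue
        feats.append(rl_features(P, npix))
    keys = feats[0].keys()
    return {k: float(np.mean([f[k] for f in feats])) for k in keys}


def glszm(lev, ng, npix):
    struct = np.ones((3, 3, 3), dtype=int)
    zones = []
    for g in range(1, ng + 1):
        lab, nlab = ndimage.label(lev == g, structure=struct)
        for z in range(1, nlab + 1):
            zones.append((g, int((lab == z).sum())))
    nz = len(zones)
    smax = max(s for _, s in zones)
    P = np.zeros((ng, smax))
    for g, s in zones:
        P[g - 1, s - 1] += 1
    i = np.arange(1, ng + 1)[:, None]
    j = np.arange(1, smax + 1)[None, :]
    p = P / nz
    pg = P.sum(1)
    ps = P.sum(0)
    mug = (i * p).sum()
    mus = (j * p).sum()
    pnz = p[p > 0]
    return {
        "SmallAreaEmphasis": (P / j ** 2).sum() / nz,
        "LargeAreaEmphasis": (P * j ** 2).sum() / nz,
        "GrayLevelNonUniformity": (pg ** 2).sum() / nz,
        "GrayLevelNonUniformityNormalized": (pg ** 2).sum() / nz ** 2,
        "SizeZoneNonUniformity": (ps ** 2).sum() / nz,
        "SizeZoneNonUniformityNormalized": (ps ** 2).sum() / nz ** 2,
        "ZonePercentage": nz / npix,
        "GrayLevelVariance": float(((i - mug) ** 2 * p).sum()),
        "ZoneVariance": float(((j - mus) ** 2 * p).sum()),
        "ZoneEntropy": float(-(pnz * np.log2(pnz)).sum()),
        "LowGrayLevelZoneEmphasis": (P / i ** 2).sum() / nz,
        "HighGrayLevelZoneEmphasis": (P * i ** 2).sum() / nz,
        "SmallAreaLowGrayLevelEmphasis": (P / (i ** 2 * j ** 2)).sum() / nz,
        "SmallAreaHighGrayLevelEmphasis": (P * i ** 2 / j ** 2).sum() / nz,
        "LargeAreaLowGrayLevelEmphasis": (P * j ** 2 / i ** 2).sum() / nz,
        "LargeAreaHighGrayLevelEmphasis": (P * i ** 2 * j ** 2).sum() / nz,
    }


def neighbours(lev, x, y, z):
    shp = lev.shape
    out = []
    for dx in (-1, 0, 1):
        for dy in (-1, 0, 1):
            for dz in (-1, 0, 1):
                if dx == dy == dz == 0:
                    continue
                xx, yy, zz = x + dx, y + dy, z + dz
                if 0 <= xx < shp[0] and 0 <= yy < shp[1] and 0 <= zz < shp[2]:
                    if lev[xx, yy, zz] > 0:
                        out.append(lev[xx, yy, zz])
    return out


def gldm(lev, ng):
    deps = []
    for x, y, z in np.argwhere(lev > 0):
        nb = neighbours(lev, x, y, z)
        d = 1 + sum(1 for v in nb if v == lev[x, y, z])
        deps.append((lev[x, y, z], d))
    dmax = max(d for _, d in deps)
    P = np.zeros((ng, dmax))
    for g, d in deps:
        P[g - 1, d - 1] += 1
    nz = P.sum()
    i = np.arange(1, ng + 1)[:, None]
    j = np.arange(1, dmax + 1)[None, :]
    p = P / nz
    pg = P.sum(1)
    pd = P.sum(0)
    mug = (i * p).sum()
    mud = (j * p).sum()
    pnz = p[p > 0]
    return {
        "SmallDependenceEmphasis": (P / j ** 2).sum() / nz,
        "LargeDependenceEmphasis": (P * j ** 2).sum() / nz,
        "GrayLevelNonUniformity": (pg ** 2).sum() / nz,
        "DependenceNonUniformity": (pd ** 2).sum() / nz,
        "DependenceNonUniformityNormalized": (pd ** 2).sum() / nz ** 2,
        "GrayLevelVariance": float(((i - mug) ** 2 * p).sum()),
        "DependenceVariance": float(((j - mud) ** 2 * p).sum()),
        "DependenceEntropy": float(-(pnz * np.log2(pnz)).sum()),
        "LowGrayLevelEmphasis": (P / i ** 2).sum() / nz,
        "HighGrayLevelEmphasis": (P * i ** 2).sum() / nz,
        "SmallDependenceLowGrayLevelEmphasis": (P / (i ** 2 * j ** 2)).sum() / nz,
        "SmallDependenceHighGrayLevelEmphasis": (P * i ** 2 / j ** 2).sum() / nz,
        "LargeDependenceLowGrayLevelEmphasis": (P * j ** 2 / i ** 2).sum() / nz,
        "LargeDependenceHighGrayLevelEmphasis": (P * i ** 2 * j ** 2).sum() / nz,
    }


def ngtdm(lev, ng):
    s = np.zeros(ng)
    n = np.zeros(ng)
    for x, y, z in np.argwhere(lev > 0):
        nb = neighbours(lev, x, y, z)
        if not nb:
            continue
        g = lev[x, y, z]
        s[g - 1] += abs(g - np.mean(nb))
        n[g - 1] += 1
    nvp = n.sum()
    p = n / nvp
    pres = np.where(p > 0)[0]
    ngp = pres.size
    lv = np.arange(1, ng + 1)
    den = (p * s).sum()
    coarseness = 1 / den if den > 0 else 1e6
    if ngp > 1:
        pi = p[pres]
        li = lv[pres]
        si = s[pres]
        dij = li[:, None] - li[None, :]
        contrast = (np.outer(pi, pi) * dij ** 2).sum() / (ngp * (ngp - 1)) \
            * s.sum() / nvp
        ipi = li * pi
        bden = np.abs(ipi[:, None] - ipi[None, :]).sum()
        busyness = den / bden if bden > 0 else 0.0
        psum = pi[:, None] + pi[None, :]
        snum = (pi * si)[:, None] + (pi * si)[None, :]
        complexity = (np.abs(dij) * snum / psum).sum() / nvp
        strength = ((psum * dij ** 2).sum() / s.sum()) if s.sum() > 0 else 0.0
    else:
        contrast = busyness = complexity = strength = 0.0
    return {"Coarseness": float(coarseness), "Contrast": float(contrast),
            "Busyness": float(busyness), "Complexity": float(complexity),
            "Strength": float(strength)}


def main():
    img_f, msk_f = sys.argv[1], sys.argv[2]
    nx, ny, nz = map(int, sys.argv[3:6])
    spacing = list(map(float, sys.argv[6:9]))
    bw = float(sys.argv[9])
    img = np.loadtxt(img_f).reshape((nx, ny, nz), order="F")
    mask = np.loadtxt(msk_f).reshape((nx, ny, nz), order="F").astype(bool)
    lev, ng = discretize(img, mask, bw)
    npix = int(mask.sum())
    out = {}
    fo = first_order(img, mask, lev, ng)
    fo["TotalEnergy"] = fo["Energy"] * float(np.prod(spacing))
    for k, v in fo.items():
        out["firstorder_" + k] = v
    for k, v in shape(mask, spacing).items():
        out["shape_" + k] = v
    for k, v in glcm(lev, ng).items():
        out["glcm_" + k] = v
    for k, v in glrlm(lev, ng, npix).items():
        out["glrlm_" + k] = v
    for k, v in glszm(lev, ng, npix).items():
        out["glszm_" + k] = v
    for k, v in gldm(lev, ng).items():
        out["gldm_" + k] = v
    for k, v in ngtdm(lev, ng).items():
        out["ngtdm_" + k] = v
    for k, v in out.items():
        print(f"{k},{float(v)!r}")


if __name__ == "__main__":
    main()
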