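"""Independent XDF chunk walker: prints '<stream_id> <n_samples>' per
stream, counting Samples-chunk entries only from the chunk framing (no
shared code with the R reader)."""
import struct
import sys
from collections import defaultdict


def main(path):
    counts = defaultdict(int)
    fmts = {}
    with open(path, "rb") as fh:
        assert fh.read(4) == b"XDF:", "bad magic"
        while True:
            nb = fh.read(1)
            if not nb:
                break
            nbytes = nb[0]
            assert nbytes in (1, 4, 8)
            length = int.from_bytes(fh.read(nbytes), "little")
            tag = struct.unpack("<H", fh.read(2))[0]
            content = fh.read(length - 2)
            assert len(content) == length - 2, "truncated"
            if tag == 2:
                sid = struct.unpack("<I", content[:4])[0]
                xml = content[4:].decode()
                fmt = xml.split("<channel_format>")[1].split("<")[0]
                nch = int(xml.split("<channel_count>")[1].split("<")[0])
                fmts[sid] = (fmt, nch)
                counts[sid] += 0
            elif tag == 3:
                sid = struct.unpack("<I", content[:4])[0]
                body = content[4:]
                pos = 0
                nvb = body[pos]
                pos += 1
                nsamp = int.from_bytes(body[pos:pos + nvb], "little")
                pos += nvb
                fmt, nch = fmts[sid]
                for _ in range(nsamp):
                    tb = body[pos]
                    pos += 1 + (8 if tb == 8 else 0)
                    if fmt == "double64":
                        pos += 8 * nch
                    else:
                        slb = body[pos]
                        pos += 1
                        slen = int.from_bytes(body[pos:pos + slb], "little")
                        pos += slb + slen
                    counts[sid] += 1
                assert pos == len(body), "sample chunk length mismatch"
    for sid in sorted(counts):
        print(sid, counts[sid])


if __name__ == "__main__":
    main(sys.argv[1])
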