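>citcol-1
VCLFVGKPCWSDADCPSGCSCKPLPLIDAGYCGFL
>citcol-2
VCLFVGKPCWSDADCPSGCYCKPLPLIDAGYCGFL
>citcol-3
VGVCLFVGKPCWSDADCPSGCSCKPLPLIDAGYCGFL
>citcol-4
VGVCLFVGKPCWSDADCPSGCYCKPLPLIDAGYCGFL
>citcol-5
RVGVCLFVGKPCWSDADCPSGCYCKPLPLIDAGYCGFL
>citcol-6
NRVGVCLFVGKPCWSDADCPSGCSCKPLPLIDAGYCGFL
>citcol-7
NRVGVCLFVGKPCKSDANCPSGCYCKPLPLIDAGYCGFL
>citcol-8
NRVGVCLFVGKPCWSDADCPSGCYCKPLPLIDAGYCGFL
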