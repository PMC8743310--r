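o S1
v 0 0 0
v 1 0 0
v 0 1 0
v 1 1 0
v 0 0 1
v 1 0 1
v 0 1 1
v 1 1 1
f 1 3 7
f 1 7 5
f 2 8 4
f 2 6 8
f 1 5 6
f 1 6 2
f 3 4 8
f 3 8 7
f 1 2 4
f 1 4 3
f 5 7 8
f 5 8 6
o S2
v 1.5 0 0
v 2.5 0 0
v 1.5 1 0
v 2.5 1 0
v 1.5 0 1
v 2.5 0 1
v 1.5 1 1
v 2.5 1 1
f 9 11 15
f 9 15 13
f 10 16 12
f 10 14 16
f 9 13 14
f 9 14 10
f 11 12 16
f 11 16 15
f 9 10 12
f 9 12 11
f 13 15 16
f 13 16 14
o S3
v 3 0 0
v 4 0 0
v 3 1 0
v 4 1 0
v 3 0 1
v 4 0 1
v 3 1 1
v 4 1 1
f 17 19 23
f 17 23 21
f 18 24 20
f 18 22 24
f 17 21 22
f 17 22 18
f 19 20 24
f 19 24 23
f 17 18 20
f 17 20 19
f 21 23 24
f 21 24 22
o S4
v 4.5 0 0
v 5.5 0 0
v 4.5 1 0
v 5.5 1 0
v 4.5 0 1
v 5.5 0 1
v 4.5 1 1
v 5.5 1 1
f 25 27 31
f 25 31 29
f 26 32 28
f 26 30 32
f 25 29 30
f 25 30 26
f 27 28 32
f 27 32 31
f 25 26 28
f 25 28 27
f 29 31 32
f 29 32 30
o S5
v 6 0 0
v 7 0 0
v 6 1 0
v 7 1 0
v 6 0 1
v 7 0 1
v 6 1 1
v 7 1 1
f 33 35 39
f 33 39 37
f 34 40 36
f 34 38 40
f 33 37 38
f 33 38 34
f 35 36 40
f 35 40 39
f 33 34 36
f 33 36 35
f 37 39 40
f 37 40 38
o S6
v 7.5 0 0
v 8.5 0 0
v 7.5 1 0
v 8.5 1 0
v 7.5 0 1
v 8.5 0 1
v 7.5 1 1
v 8.5 1 1
f 41 43 47
f 41 47 45
f 42 48 44
f 42 46 48
f 41 45 46
f 41 46 42
f 43 44 48
f 43 48 47
f 41 42 44
f 41 44 43
f 45 47 48
f 45 48 46
o S7
v 0 0 1.5
v 1 0 1.5
v 0 1 1.5
v 1 1 1.5
v 0 0 2.5
v 1 0 2.5
v 0 1 2.5
v 1 1 2.5
f 49 51 55
f 49 55 53
f 50 56 52
f 50 54 56
f 49 53 54
f 49 54 50
f 51 52 56
f 51 56 55
f 49 50 52
f 49 52 51
f 53 55 56
f 53 56 54
o S8
v 1.5 0 1.5
v 2.5 0 1.5
v 1.5 1 1.5
v 2.5 1 1.5
v 1.5 0 2.5
v 2.5 0 2.5
v 1.5 1 2.5
v 2.5 1 2.5
f 57 59 63
f 57 63 61
f 58 64 60
f 58 62 64
f 57 61 62
f 57 62 58
f 59 60 64
f 59 64 63
f 57 58 60
f 57 60 59
f 61 63 64
f 61 64 62
o S9
v 3 0 1.5
v 4 0 1.5
v 3 1 1.5
v 4 1 1.5
v 3 0 2.5
v 4 0 2.5
v 3 1 2.5
v 4 1 2.5
f 65 67 71
f 65 71 69
f 66 72 68
f 66 70 72
f 65 69 70
f 65 70 66
f 67 68 72
f 67 72 71
f 65 66 68
f 65 68 67
f 69 71 72
f 69 72 70
o S10
v 4.5 0 1.5
v 5.5 0 1.5
v 4.5 1 1.5
v 5.5 1 1.5
v 4.5 0 2.5
v 5.5 0 2.5
v 4.5 1 2.5
v 5.5 1 2.5
f 73 75 79
f 73 79 77
f 74 80 76
f 74 78 80
f 73 77 78
f 73 78 74
f 75 76 80
f 75 80 79
f 73 74 76
f 73 76 75
f 77 79 80
f 77 80 78
o S11
v 6 0 1.5
v 7 0 1.5
v 6 1 1.5
v 7 1 1.5
v 6 0 2.5
v 7 0 2.5
v 6 1 2.5
v 7 1 2.5
f 81 83 87
f 81 87 85
f 82 88 84
f 82 86 88
f 81 85 86
f 81 86 82
f 83 84 88
f 83 88 87
f 81 82 84
f 81 84 83
f 85 87 88
f 85 88 86
o S12
v 7.5 0 1.5
v 8.5 0 1.5
v 7.5 1 1.5
v 8.5 1 1.5
v 7.5 0 2.5
v 8.5 0 2.5
v 7.5 1 2.5
v 8.5 1 2.5
f 89 91 95
f 89 95 93
f 90 96 92
f 90 94 96
f 89 93 94
f 89 94 90
f 91 92 96
f 91 96 95
f 89 90 92
f 89 92 91
f 93 95 96
f 93 96 94
o S13
v 0 0 3
v 1 0 3
v 0 1 3
v 1 1 3
v 0 0 4
v 1 0 4
v 0 1 4
v 1 1 4
f 97 99 103
f 97 103 101
f 98 104 100
f 98 102 104
f 97 101 102
f 97 102 98
f 99 100 104
f 99 104 103
f 97 98 100
f 97 100 99
f 101 103 104
f 101 104 102
o S14
v 1.5 0 3
v 2.5 0 3
v 1.5 1 3
v 2.5 1 3
v 1.5 0 4
v 2.5 0 4
v 1.5 1 4
v 2.5 1 4
f 105 107 111
f 105 111 109
f 106 112 108
f 106 110 112
f 105 109 110
f 105 110 106
f 107 108 112
f 107 112 111
f 105 106 108
f 105 108 107
f 109 111 112
f 109 112 110
o S15
v 3 0 3
v 4 0 3
v 3 1 3
v 4 1 3
v 3 0 4
v 4 0 4
v 3 1 4
v 4 1 4
f 113 115 119
f 113 119 117
f 114 120 116
f 114 118 120
f 113 117 118
f 113 118 114
f 115 116 120
f 115 120 119
f 113 114 116
f 113 116 115
f 117 119 120
f 117 120 118
o S16
v 4.5 0 3
v 5.5 0 3
v 4.5 1 3
v 5.5 1 3
v 4.5 0 4
v 5.5 0 4
v 4.5 1 4
v 5.5 1 4
f 121 123 127
f 121 127 125
f 122 128 124
f 122 126 128
f 121 125 126
f 121 126 122
f 123 124 128
f 123 128 127
f 121 122 124
f 121 124 123
f 125 127 128
f 125 128 126
o S17
v 6 0 3
v 7 0 3
v 6 1 3
v 7 1 3
v 6 0 4
v 7 0 4
v 6 1 4
v 7 1 4
f 129 131 135
f 129 135 133
f 130 136 132
f 130 134 136
f 129 133 134
f 129 134 130
f 131 132 136
f 131 136 135
f 129 130 132
f 129 132 131
f 133 135 136
f 133 136 134
o S18
v 7.5 0 3
v 8.5 0 3
v 7.5 1 3
v 8.5 1 3
v 7.5 0 4
v 8.5 0 4
v 7.5 1 4
v 8.5 1 4
f 137 139 143
f 137 143 141
f 138 144 140
f 138 142 144
f 137 141 142
f 137 142 138
f 139 140 144
f 139 144 143
f 137 138 140
f 137 140 139
f 141 143 144
f 141 144 142
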